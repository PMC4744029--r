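#' Read a weighted graph from a plain-text file
#'
#' Two dialects are supported. `"edgelist"` is a whitespace-separated file
#' with one `<node> <node> <weight>` triple per line; `#` starts a comment.
#' A comment of the form `# nodes: a b c` (as written by
#' [write_edge_list()]) declares the full node set, so isolated nodes
#' survive a round trip. `"pajek"` is the Pajek .net format: a
#' `*Vertices n` block of `index ["label"]` lines followed by an `*Edges`
#' block of `i j w` triples; indices are mapped to labels (or to the index
#' as a string when no label is given), so node identifiers stay opaque.
#'
#' @param path file to read.
#' @param dialect `"edgelist"` or `"pajek"`.
#' @param duplicate_policy what to do when the same unordered pair occurs on
#'   several lines: `"error"` (default) rejects the file, `"sum"` adds the
#'   weights (useful for raw multigraph dumps).
#' @return a [wgraph].
#' @export
read_edge_list <- function(path, dialect = c("edgelist", "pajek"),
                           duplicate_policy = c("error", "sum")) {
  dialect <- match.arg(dialect)
  duplicate_policy <- match.arg(duplicate_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  parsed <- switch(dialect,
    edgelist = .parse_edgelist(lines, path),
    pajek = .parse_pajek(lines, path))
  ed <- parsed$edges
  if (nrow(ed) > 0) {
    if (any(ed$from == ed$to)) {
      bad <- parsed$lineno[ed$from == ed$to][1]
      stop(sprintf("%s:%d: self-loop is not allowed", path, bad))
    }
    if (any(!is.finite(ed$weight)) || any(ed$weight <= 0)) {
      bad <- parsed$lineno[!is.finite(ed$weight) | ed$weight <= 0][1]
      stop(sprintf("%s:%d: link weight must be strictly positive", path, bad))
    }
    key <- pair_key(ed$from, ed$to)
    if (anyDuplicated(key)) {
      if (duplicate_policy == "error") {
        bad <- parsed$lineno[duplicated(key)][1]
        stop(sprintf("%s:%d: duplicate link (set duplicate_policy = \"sum\" to aggregate)",
                     path, bad))
      }
      agg <- rowsum(ed$weight, key)
      first <- !duplicated(key)
      ed <- ed[first, , drop = FALSE]
      ed$weight <- agg[match(pair_key(ed$from, ed$to), rownames(agg)), 1]
    }
  }
  wgraph(ed, nodes = parsed$nodes)
}

.parse_edgelist <- function(lines, path) {
  nodes <- NULL
  from <- to <- character(0)
  w <- numeric(0)
  lineno <- integer(0)
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (nchar(line) == 0) next
    if (startsWith(line, "#")) {
      body <- trimws(sub("^#+", "", line))
      if (startsWith(body, "nodes:")) {
        nodes <- strsplit(trimws(sub("^nodes:", "", body)), "[[:space:]]+")[[1]]
      }
      next
    }
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(tok) != 3) {
      stop(sprintf("%s:%d: expected `<node> <node> <weight>`, got %d field(s)",
                   path, k, length(tok)))
    }
    wk <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(wk)) stop(sprintf("%s:%d: weight `%s` is not a number", path, k, tok[3]))
    from <- c(from, tok[1]); to <- c(to, tok[2]); w <- c(w, wk)
    lineno <- c(lineno, k)
  }
  if (!is.null(nodes)) nodes <- union(nodes, c(from, to))
  list(edges = data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE),
       nodes = nodes, lineno = lineno)
}

.parse_pajek <- function(lines, path) {
  header <- grep("^\\*[Vv]ertices", lines)
  if (length(header) != 1) stop(path, ": expected exactly one *Vertices block")
  n <- suppressWarnings(as.integer(strsplit(trimws(lines[header]),
                                            "[[:space:]]+")[[1]][2]))
  if (is.na(n)) stop(sprintf("%s:%d: malformed *Vertices header", path, header))
  estart <- grep("^\\*([Ee]dges|[Aa]rcs)", lines)
  if (length(estart) < 1) stop(path, ": no *Edges block")
  estart <- estart[1]
  labels <- as.character(seq_len(n))
  for (k in seq.int(header + 1, length.out = max(0, estart - header - 1))) {
    line <- trimws(lines[k])
    if (nchar(line) == 0 || startsWith(line, "%")) next
    m <- regmatches(line, regexec('^([0-9]+)[[:space:]]+"([^"]*)"', line))[[1]]
    if (length(m) == 3) {
      labels[as.integer(m[2])] <- m[3]
    } else {
      idx <- suppressWarnings(as.integer(strsplit(line, "[[:space:]]+")[[1]][1]))
      if (is.na(idx) || idx < 1 || idx > n) {
        stop(sprintf("%s:%d: malformed vertex line", path, k))
      }
    }
  }
  from <- to <- character(0)
  w <- numeric(0)
  lineno <- integer(0)
  for (k in seq.int(estart + 1, length.out = max(0, length(lines) - estart))) {
    line <- trimws(lines[k])
    if (nchar(line) == 0 || startsWith(line, "%")) next
    if (startsWith(line, "*")) break
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(tok) < 2) stop(sprintf("%s:%d: expected `i j [w]`", path, k))
    i <- suppressWarnings(as.integer(tok[1]))
    j <- suppressWarnings(as.integer(tok[2]))
    wk <- if (length(tok) >= 3) suppressWarnings(as.numeric(tok[3])) else 1
    if (is.na(i) || is.na(j) || i < 1 || j < 1 || i > n || j > n) {
      stop(sprintf("%s:%d: vertex index out of range", path, k))
    }
    if (is.na(wk)) stop(sprintf("%s:%d: weight `%s` is not a number", path, k, tok[3]))
    from <- c(from, labels[i]); to <- c(to, labels[j]); w <- c(w, wk)
    lineno <- c(lineno, k)
  }
  list(edges = data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE),
       nodes = labels, lineno = lineno)
}

#' Write a weighted graph to a plain-text file
#'
#' Weights are serialised with full precision (17 significant digits), so
#' `read_edge_list(write_edge_list(g))` reproduces `g` exactly up to node
#' ordering. The edgelist dialect records the node set in a `# nodes:`
#' comment so isolated nodes round-trip too.
#'
#' @param g a [wgraph].
#' @param path file to write.
#' @param dialect `"edgelist"` or `"pajek"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, dialect = c("edgelist", "pajek")) {
  dialect <- match.arg(dialect)
  validate_wgraph(g)
  ed <- graph_edges(g)
  nm <- graph_nodes(g)
  lines <- if (dialect == "edgelist") {
    c(paste("# nodes:", paste(nm, collapse = " ")),
      sprintf("%s %s %.17g", ed$from, ed$to, ed$weight))
  } else {
    idx <- stats::setNames(seq_along(nm), nm)
    c(sprintf("*Vertices %d", length(nm)),
      sprintf('%d "%s"', seq_along(nm), nm),
      "*Edges",
      sprintf("%d %d %.17g", idx[ed$from], idx[ed$to], ed$weight))
  }
  writeLines(lines, path)
  invisible(path)
}
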