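#' Build a PPI network from an edge data frame
#'
#' Constructs the undirected, simple (no self-loops, no duplicate edges)
#' network all other functions in the package operate on.  Self-loops and
#' duplicate edges are dropped silently; their counts are kept as graph
#' attributes `n_selfloops_dropped` and `n_duplicates_dropped`.
#'
#' @param edges two-column character data frame (or matrix) of endpoints.
#' @param nodes optional character vector of additional isolated nodes.
#' @return an undirected simple [igraph::igraph] with named vertices.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  u <- as.character(edges[[1]])
  v <- as.character(edges[[2]])
  if (any(!nzchar(u)) || any(!nzchar(v)))
    stop("empty node identifier in edge list")
  loops <- u == v
  u2 <- u[!loops]; v2 <- v[!loops]
  ## canonical unordered pair for duplicate detection
  key <- ifelse(u2 < v2, paste(u2, v2, sep = "\r"), paste(v2, u2, sep = "\r"))
  dup <- duplicated(key)
  u2 <- u2[!dup]; v2 <- v2[!dup]
  ## canonical orientation and order: edge list is input-order invariant
  sw <- u2 > v2
  tmp <- u2[sw]; u2[sw] <- v2[sw]; v2[sw] <- tmp
  o <- order(u2, v2, method = "radix")
  u2 <- u2[o]; v2 <- v2[o]
  vs <- lex_sort(unique(c(u2, v2, u[loops], nodes)))
  g <- igraph::make_empty_graph(n = length(vs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vs)
  if (length(u2))
    g <- igraph::add_edges(g, rbind(u2, v2))
  g <- igraph::set_graph_attr(g, "n_selfloops_dropped", sum(loops))
  g <- igraph::set_graph_attr(g, "n_duplicates_dropped", sum(dup))
  g
}

#' Read a PPI network from an edge-list file
#'
#' Supports a whitespace/tab-separated two-column edge list (`format = "tsv"`,
#' extra columns ignored) and the Cytoscape SIF dialect (`format = "sif"`:
#' `node relation node [node ...]`, one edge per listed target).  Lines that
#' are blank or start with `#` are skipped.
#'
#' @param path file path.
#' @param format `"tsv"` or `"sif"`.
#' @return an undirected simple igraph (see [ppi_network()]).
#' @export
read_network <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("empty network file: ", path)
  ul <- vl <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (format == "tsv") {
      if (length(f) < 2)
        stop("malformed edge line ", ln, " in ", path, ": ", lines[ln])
      ul[[i]] <- f[1]; vl[[i]] <- f[2]
    } else {
      if (length(f) == 1) { ul[[i]] <- character(); vl[[i]] <- character(); next }
      if (length(f) < 3)
        stop("malformed SIF line ", ln, " in ", path, ": ", lines[ln])
      ul[[i]] <- rep(f[1], length(f) - 2); vl[[i]] <- f[-(1:2)]
    }
  }
  u <- unlist(ul); v <- unlist(vl)
  if (!length(u)) stop("no edges in network file: ", path)
  ppi_network(data.frame(u = u, v = v, stringsAsFactors = FALSE))
}

#' Read a gene set (one identifier per line)
#'
#' Blank lines and lines starting with `#` are ignored; duplicates collapsed.
#' Identifiers are opaque, case-sensitive strings.
#'
#' @param path file path.
#' @param name set name (defaults to the file base name).
#' @return a `gene_set`: list with `name` and character `members`.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  members <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (!length(members)) stop("no gene identifiers in ", path)
  gene_set(name, members)
}

#' @rdname read_gene_set
#' @param members character vector of gene identifiers.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (any(!nzchar(members))) stop("empty gene identifier in set '", name, "'")
  structure(list(name = name, members = members), class = "gene_set")
}

#' Read gene sets in GMT format
#'
#' Each tab-separated line is `name<TAB>description<TAB>member...`; the
#' description is discarded.
#'
#' @param path file path.
#' @return list of `gene_set` objects, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " (need name, description, >=1 member)")
    gene_set(f[1], f[-(1:2)])
  })
}

#' Write a detected module, trace and edit log to a directory
#'
#' Writes `nodes.tsv` (`node`, `role` seed/expanded), `edges.tsv`
#' (`u`, `v`, `origin` original/added), `edit_log.tsv` and, when present,
#' `trace.tsv`.  Output is byte-identical across runs with identical inputs.
#'
#' @param fit an [idmcss()] fit, or a `disease_module`.
#' @param dir output directory (created if absent).
#' @param seeds character vector of seed identifiers (taken from the fit when
#'   omitted).
#' @return invisibly, the directory.
#' @export
write_module <- function(fit, dir, seeds = NULL) {
  if (inherits(fit, "idmcss")) {
    mod <- fit$module
    seeds <- seeds %||% fit$S0
    log <- fit$edit_log
    trace <- fit$trace
  } else {
    mod <- fit
    seeds <- seeds %||% character()
    log <- empty_edit_log()
    trace <- NULL
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- lex_sort(mod$nodes)
  nd <- data.frame(node = nodes,
                   role = ifelse(nodes %in% seeds, "seed", "expanded"),
                   stringsAsFactors = FALSE)
  ed <- mod$edges
  if (nrow(ed)) {
    sw <- ed$u > ed$v
    tmp <- ed$u[sw]; ed$u[sw] <- ed$v[sw]; ed$v[sw] <- tmp
    ed <- ed[order(ed$u, ed$v, method = "radix"), , drop = FALSE]
    added_key <- character()
    if (nrow(log)) {
      add <- log[log$action == "add", , drop = FALSE]
      added_key <- pair_key(add$u, add$v)
    }
    ed$origin <- ifelse(pair_key(ed$u, ed$v) %in% added_key, "added", "original")
  } else {
    ed$origin <- character()
  }
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE, eol = "\n")
  wt(nd, "nodes.tsv")
  wt(ed, "edges.tsv")
  wt(log, "edit_log.tsv")
  if (!is.null(trace)) wt(format(trace, digits = 15, trim = TRUE), "trace.tsv")
  invisible(dir)
}

## canonical key of an unordered node pair
pair_key <- function(u, v) ifelse(u < v, paste(u, v, sep = "\r"),
                                  paste(v, u, sep = "\r"))

empty_edit_log <- function() {
  data.frame(u = character(), v = character(), action = character(),
             iteration = integer(), semantic_similarity = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$members), " members\n", sep = "")
  invisible(x)
}
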