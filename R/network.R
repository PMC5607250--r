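#' Build a miRNA-gene(-pathway) regulation network
#'
#' Nodes are typed (`miRNA`, `gene`, `pathway`); `regulates` edges run
#' miRNA to gene and `participates_in` edges run gene to pathway. Rows with
#' a blank or missing endpoint are rejected (and reported in the
#' `rejected` attribute); duplicate edges are collapsed. When `de_set` is
#' given the miRNA-gene table is first restricted to those miRNAs.
#'
#' @param mirna_gene Data frame whose first two columns are miRNA and gene
#'   ids (a `score` column, if present, is ignored).
#' @param gene_pathway Optional data frame whose first two columns are gene
#'   and pathway ids; makes the network tripartite.
#' @param de_set Optional character vector of miRNA ids to keep.
#' @return A list of class `"network_spec"` with `nodes` (data frame `id`,
#'   `kind`) and `edges` (data frame `source`, `target`, `kind`).
#' @export
build_network <- function(mirna_gene, gene_pathway = NULL, de_set = NULL) {
  if (is.null(mirna_gene) || nrow(mirna_gene) == 0) {
    stop("miRNA-gene edge table must be non-empty")
  }
  clean <- function(df) {
    a <- trimws(as.character(df[[1]])); b <- trimws(as.character(df[[2]]))
    bad <- is.na(a) | is.na(b) | a == "" | b == ""
    list(a = a[!bad], b = b[!bad], n_rejected = sum(bad))
  }
  mg <- clean(mirna_gene)
  rejected <- mg$n_rejected
  if (!is.null(de_set)) {
    keep <- mg$a %in% de_set
    mg$a <- mg$a[keep]; mg$b <- mg$b[keep]
  }
  edges <- unique(data.frame(source = mg$a, target = mg$b, kind = "regulates",
                             stringsAsFactors = FALSE))
  nodes <- rbind(
    data.frame(id = unique(mg$a), kind = "miRNA", stringsAsFactors = FALSE),
    data.frame(id = unique(mg$b), kind = "gene", stringsAsFactors = FALSE))
  if (!is.null(gene_pathway) && nrow(gene_pathway) > 0) {
    gp <- clean(gene_pathway)
    rejected <- rejected + gp$n_rejected
    keep <- gp$a %in% nodes$id[nodes$kind == "gene"]
    e2 <- unique(data.frame(source = gp$a[keep], target = gp$b[keep],
                            kind = "participates_in", stringsAsFactors = FALSE))
    edges <- rbind(edges, e2)
    nodes <- rbind(nodes, data.frame(id = setdiff(unique(e2$target), nodes$id),
                                     kind = "pathway", stringsAsFactors = FALSE))
  }
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  edges <- edges[order(edges$kind, edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  attr(out, "rejected") <- rejected
  class(out) <- "network_spec"
  out
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$kind),
                            names(table(x$nodes$kind))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Degree and hub summary of a regulation network
#'
#' @param net A `"network_spec"`.
#' @param k Hub threshold: miRNAs regulating at least `k` genes, genes
#'   targeted by at least `k` miRNAs, genes in at least `k` pathways.
#' @return List with `n_nodes`, `n_edges`, `nodes_by_kind`, `degree` (data
#'   frame `id`, `kind`, `degree`), and `hubs` (list `mirnas`, `genes`,
#'   `pathway_genes`).
#' @export
network_stats <- function(net, k = 4L) {
  stopifnot(inherits(net, "network_spec"))
  deg <- table(factor(c(net$edges$source, net$edges$target),
                      levels = net$nodes$id))
  reg <- net$edges[net$edges$kind == "regulates", , drop = FALSE]
  par <- net$edges[net$edges$kind == "participates_in", , drop = FALSE]
  out_mirna <- table(factor(reg$source,
                            levels = net$nodes$id[net$nodes$kind == "miRNA"]))
  in_gene <- table(factor(reg$target,
                          levels = net$nodes$id[net$nodes$kind == "gene"]))
  gene_pw <- table(factor(par$source,
                          levels = net$nodes$id[net$nodes$kind == "gene"]))
  list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
       nodes_by_kind = table(net$nodes$kind),
       degree = data.frame(id = net$nodes$id, kind = net$nodes$kind,
                           degree = as.integer(deg[net$nodes$id]),
                           stringsAsFactors = FALSE),
       hubs = list(mirnas = names(out_mirna)[out_mirna >= k],
                   genes = names(in_gene)[in_gene >= k],
                   pathway_genes = names(gene_pw)[gene_pw >= k]))
}

#' Export a regulation network
#'
#' Formats: `sif` (one `source<TAB>kind<TAB>target` line per edge),
#' `graphml` (via igraph, node/edge `kind` attributes preserved), `tsv`
#' (edge table with a `kind` column). All three round-trip losslessly
#' through [import_graph()].
#'
#' @param net A `"network_spec"`.
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "network_spec"))
  if (format == "sif") {
    writeLines(paste(net$edges$source, net$edges$kind, net$edges$target,
                     sep = "\t"), path)
  } else if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = TRUE,
      vertices = data.frame(name = net$nodes$id, kind = net$nodes$kind,
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a regulation network written by [export_graph()]
#'
#' @param path Input file path.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return A `"network_spec"`.
#' @export
import_graph <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    f <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("source", "kind", "target"),
                           stringsAsFactors = FALSE)
    edges <- f[, c("source", "target", "kind")]
  } else if (format == "tsv") {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "both")
    edges <- data.frame(source = df$edges$from, target = df$edges$to,
                        kind = df$edges$kind, stringsAsFactors = FALSE)
    nodes <- data.frame(id = df$vertices$name, kind = df$vertices$kind,
                        stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
    edges <- edges[order(edges$kind, edges$source, edges$target), , drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    out <- list(nodes = nodes, edges = edges)
    class(out) <- "network_spec"
    return(out)
  }
  # Node kinds are implied by edge kinds (regulates: miRNA -> gene;
  # participates_in: gene -> pathway).
  reg <- edges[edges$kind == "regulates", , drop = FALSE]
  par <- edges[edges$kind == "participates_in", , drop = FALSE]
  nodes <- rbind(
    data.frame(id = unique(reg$source), kind = "miRNA", stringsAsFactors = FALSE),
    data.frame(id = unique(c(reg$target, par$source)), kind = "gene",
               stringsAsFactors = FALSE),
    data.frame(id = unique(par$target), kind = "pathway",
               stringsAsFactors = FALSE))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  edges <- edges[order(edges$kind, edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "network_spec"
  out
}
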