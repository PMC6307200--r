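# Merged protein-protein interaction graph, ADAR neighbourhood,
# permutation enrichment, node centrality.

#' Default ADAR-family seed node ids
#'
#' ADAR (ADAR1), ADARB1 (ADAR2) and ADARB2 (ADAR3). All three seed the
#' neighbourhood; analyses that distinguish ADAR1/ADAR2 can pass the first
#' two only.
#' @return character vector.
#' @export
adar_seed_ids <- function() c("ADAR", "ADARB1", "ADARB2")

parse_ppi_dialect <- function(x, dialect, string_min_score,
                              string_evidence_cols, biogrid_physical_only) {
  d <- if (is.character(x) && length(x) == 1L) read_tsv(x) else
    as.data.frame(x)
  file_tag <- if (is.character(x)) x else dialect
  if (dialect == "string") {
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% names(d)))
      stop("unknown column layout for STRING-dialect file '", file_tag,
           "': expected ", paste(need, collapse = ", "), call. = FALSE)
    keep <- d$combined_score > string_min_score  # strictly above
    if (length(string_evidence_cols)) {
      have <- intersect(string_evidence_cols, names(d))
      if (length(have))
        keep <- keep & Reduce(`|`, lapply(have, function(cl) d[[cl]] > 0))
    }
    d <- d[keep, , drop = FALSE]
    data.frame(a = d$protein1, b = d$protein2, source = "string",
               score = d$combined_score)
  } else if (dialect == "biogrid") {
    need <- c("gene_a", "gene_b", "evidence")
    if (!all(need %in% names(d)))
      stop("unknown column layout for BioGRID-dialect file '", file_tag,
           "': expected ", paste(need, collapse = ", "), call. = FALSE)
    if (biogrid_physical_only) d <- d[d$evidence == "physical", ,
                                      drop = FALSE]
    data.frame(a = d$gene_a, b = d$gene_b, source = "biogrid",
               score = NA_real_)
  } else if (dialect == "bioplex") {
    need <- c("gene_a", "gene_b")
    if (!all(need %in% names(d)))
      stop("unknown column layout for BioPlex-dialect file '", file_tag,
           "': expected ", paste(need, collapse = ", "), call. = FALSE)
    data.frame(a = d$gene_a, b = d$gene_b, source = "bioplex",
               score = NA_real_)
  } else stop("unknown PPI dialect: ", dialect, call. = FALSE)
}

#' Build a merged PPI graph from three source dialects
#'
#' Applies the per-source filters (STRING: combined score strictly above
#' `string_min_score` and at least one allowed evidence channel positive;
#' BioGRID: physical interactions only), merges the edge lists into an
#' undirected simple graph (parallel edges collapsed with their sources
#' recorded, self-loops dropped) and removes blacklisted nodes (e.g. the
#' ubiquitin gene family) with all their edges.
#'
#' @param edge_files named list with elements `string`, `biogrid`,
#'   `bioplex`; each a TSV path or data.frame. Expected columns:
#'   STRING-dialect `protein1, protein2, combined_score` (+ optional
#'   evidence-channel columns); BioGRID-dialect `gene_a, gene_b, evidence`;
#'   BioPlex-dialect `gene_a, gene_b`.
#' @param string_min_score strict lower bound on the combined score
#'   (default 400).
#' @param string_evidence_cols evidence-channel columns, at least one of
#'   which must be positive (default `c("experimental", "database")`;
#'   ignored when the file has none of them).
#' @param biogrid_physical_only drop non-physical BioGRID edges
#'   (default TRUE).
#' @param node_blacklist node ids to remove.
#' @return an `igraph` undirected simple graph with edge attribute
#'   `sources` (comma-joined).
#' @export
build_ppi <- function(edge_files, string_min_score = 400,
                      string_evidence_cols = c("experimental", "database"),
                      biogrid_physical_only = TRUE,
                      node_blacklist = NULL) {
  stopifnot(is.list(edge_files))
  edges <- do.call(rbind, lapply(names(edge_files), function(dl)
    parse_ppi_dialect(edge_files[[dl]], dl, string_min_score,
                      string_evidence_cols, biogrid_physical_only)))
  edges$a <- as.character(edges$a); edges$b <- as.character(edges$b)
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (length(node_blacklist))
    edges <- edges[!(edges$a %in% node_blacklist |
                       edges$b %in% node_blacklist), , drop = FALSE]
  # canonical unordered key to merge duplicates across sources
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b, sep = "|"),
                paste(edges$b, edges$a, sep = "|"))
  src <- tapply(edges$source, key, function(s)
    paste(sort(unique(s)), collapse = ","))
  uk <- names(src)
  ab <- do.call(rbind, strsplit(uk, "|", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ab[, 1], to = ab[, 2], sources = unname(src)),
    directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Direct and one-intermediate ADAR neighbourhoods
#'
#' @param graph an igraph PPI graph.
#' @param seed_nodes ADAR-family node ids (default [adar_seed_ids()]);
#'   seeds absent from the graph are ignored, but at least one must be
#'   present.
#' @return list with `direct` (1-hop neighbours of any seed) and
#'   `connected` (nodes within hop distance 2 of any seed), both excluding
#'   the seeds themselves, plus `seeds_present`.
#' @export
adar_neighborhood <- function(graph, seed_nodes = adar_seed_ids()) {
  present <- intersect(seed_nodes, igraph::V(graph)$name)
  if (length(present) == 0L)
    stop("no seed node present in the graph", call. = FALSE)
  nb1 <- unique(unlist(lapply(
    igraph::ego(graph, order = 1, nodes = present), names)))
  nb2 <- unique(unlist(lapply(
    igraph::ego(graph, order = 2, nodes = present), names)))
  list(direct = setdiff(nb1, present),
       connected = setdiff(nb2, present),
       seeds_present = present)
}

#' Count genes connected to the ADAR neighbourhood
#'
#' @param gene_set gene ids.
#' @param neighborhood result of [adar_neighborhood()].
#' @return number of `gene_set` members in the connected (hop <= 2) set;
#'   genes absent from the graph count as not connected.
#' @export
count_connected <- function(gene_set, neighborhood) {
  length(intersect(unique(gene_set), neighborhood$connected))
}

#' Permutation test for enrichment of ADAR-connected genes
#'
#' Draws `n_draws` random groups of `n_pick` genes from the background
#' (uniformly, without replacement within a draw) and counts, for each
#' group, how many members are connected to the ADAR neighbourhood. The
#' empirical p-value is (number of draws with a count >= observed + 1) /
#' (n_draws + 1): the +1 continuity correction keeps the p-value valid
#' (never exactly zero) and conservative.
#'
#' @param graph igraph PPI graph (used to derive the connected set unless
#'   `connected` is given).
#' @param background background gene ids to sample from.
#' @param n_pick group size (e.g. the number of significant genes).
#' @param observed observed connected count (e.g. from
#'   [count_connected()]).
#' @param n_draws number of random groups (default 1e6).
#' @param seed RNG seed (optional).
#' @param seed_nodes ADAR seed ids for the neighbourhood.
#' @param connected optional pre-computed connected set (overrides
#'   `graph`).
#' @param keep_null keep the full null distribution of counts.
#' @return object of class `enrichment_outcome`: list with `observed`,
#'   `n_draws`, `n_ge_observed`, `p`, and optionally `null_counts`.
#' @export
permutation_enrichment <- function(graph = NULL, background, n_pick,
                                   observed, n_draws = 1e6, seed = NULL,
                                   seed_nodes = adar_seed_ids(),
                                   connected = NULL, keep_null = FALSE) {
  if (is.null(connected))
    connected <- adar_neighborhood(graph, seed_nodes)$connected
  background <- unique(background)
  N <- length(background)
  if (n_pick > N) stop("n_pick exceeds background size", call. = FALSE)
  if (observed > n_pick) stop("observed count exceeds n_pick",
                              call. = FALSE)
  if (n_draws < 100) warning("fewer than 100 draws: empirical p is coarse")
  if (!is.null(seed)) set.seed(seed)
  is_conn <- background %in% connected
  counts <- integer(n_draws)
  for (b in seq_len(n_draws))
    counts[b] <- sum(is_conn[sample.int(N, n_pick)])
  nge <- sum(counts >= observed)
  out <- list(observed = observed, n_draws = n_draws, n_ge_observed = nge,
              p = (nge + 1) / (n_draws + 1))
  if (keep_null) out$null_counts <- counts
  class(out) <- "enrichment_outcome"
  out
}

#' @export
print.enrichment_outcome <- function(x, ...) {
  cat("<enrichment_outcome> observed =", x$observed, "; draws >= observed:",
      x$n_ge_observed, "of", x$n_draws, "; empirical p =",
      signif(x$p, 4), "\n")
  invisible(x)
}

#' Degree and normalised betweenness centrality per node
#'
#' Betweenness is normalised by 2 / ((n - 1)(n - 2)) so values lie in
#' \[0, 1\]; components are handled independently (unreachable pairs
#' contribute no paths). Graphs with fewer than 3 nodes get betweenness 0.
#'
#' @param graph igraph undirected graph.
#' @return data.frame with `node`, `degree`, `betweenness`.
#' @export
node_statistics <- function(graph) {
  n <- igraph::vcount(graph)
  btw <- if (n < 3) rep(0, n) else
    igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
  data.frame(node = igraph::V(graph)$name,
             degree = unname(igraph::degree(graph)),
             betweenness = unname(btw), row.names = NULL)
}

#' Reconstruct the ADAR-centred subnetwork for a significant gene set
#'
#' The subnetwork contains the significant genes connected to the ADAR
#' neighbourhood, the seeds themselves, and the "added partners": first
#' level interactors that link significant genes to the seeds but are not
#' significant themselves. Its node count satisfies
#' `n_connected + n_seeds + n_added_partners = total`.
#'
#' @param graph igraph PPI graph.
#' @param gene_set significant gene ids.
#' @param seed_nodes ADAR seed ids.
#' @return list with `subgraph` (igraph), `connected_genes`,
#'   `added_partners`, `seeds`, and `composition` (named counts).
#' @export
reconstruct_subnetwork <- function(graph, gene_set,
                                   seed_nodes = adar_seed_ids()) {
  nb <- adar_neighborhood(graph, seed_nodes)
  conn <- intersect(unique(gene_set), nb$connected)
  # partners: direct seed interactors adjacent to a connected gene (or
  # themselves connected genes' bridge), not significant, not seeds
  bridges <- intersect(nb$direct, setdiff(
    unique(unlist(lapply(igraph::ego(graph, 1, nodes = conn), names))),
    character(0)))
  partners <- setdiff(bridges, c(conn, nb$seeds_present))
  nodes <- unique(c(conn, partners, nb$seeds_present))
  sg <- igraph::induced_subgraph(graph, nodes)
  list(subgraph = sg, connected_genes = conn, added_partners = partners,
       seeds = nb$seeds_present,
       composition = c(n_connected = length(conn),
                       n_seeds = length(nb$seeds_present),
                       n_added_partners = length(partners),
                       total = length(nodes)))
}
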