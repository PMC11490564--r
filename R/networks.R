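#' Pairwise Spearman correlations between ASVs
#'
#' Rank correlations (average-rank ties) on per-sample relative abundances,
#' with two-sided p-values from the t approximation. Pairs involving a
#' constant ASV are returned as `NA`.
#'
#' @param table A `count_table` (>= 5 samples).
#' @param other Optional second `count_table` on the same samples; when
#'   given, correlations are computed between the columns of `table` and the
#'   columns of `other` (each kingdom closed separately).
#' @return List with matrices `rho` and `p`.
#' @export
spearman_correlations <- function(table, other = NULL) {
  x <- rel_abundance(table)
  if (nrow(x) < 5) stop("need at least 5 samples")
  n <- nrow(x)
  rx <- apply(x, 2, rank)
  if (is.null(other)) {
    rho <- suppressWarnings(stats::cor(rx))
    diag(rho) <- 1
  } else {
    y <- rel_abundance(other)
    stopifnot(nrow(y) == n)
    rho <- suppressWarnings(stats::cor(rx, apply(y, 2, rank)))
  }
  rho[!is.finite(rho)] <- NA
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  if (is.null(other)) diag(p) <- NA
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction of a p-value vector.
#'
#' @param p Vector of p-values in (0, 1\].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p > 0 & p <= 1)
  if (!all(ok)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' FDR-adjust a symmetric p-value matrix
#'
#' Benjamini-Hochberg adjustment over the upper-triangle pool of unique
#' pairs, mirrored back to a symmetric matrix (diagonal NA).
#'
#' @param p Symmetric p-value matrix.
#' @return Symmetric q-value matrix.
#' @export
fdr_adjust_matrix <- function(p) {
  q <- p
  ut <- upper.tri(p)
  q[ut] <- bh_adjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- NA
  q
}

#' Build the dual-method consensus co-occurrence network
#'
#' An edge joins two ASVs iff `|rho| > corr_threshold`,
#' `|sparcc r| > corr_threshold`, and both FDR-corrected p-values are below
#' `alpha`. Edges where the two methods disagree in sign are dropped with a
#' warning. Nodes are all ASVs of the correlation matrices.
#'
#' @param rho,r_sparcc Correlation matrices (same dimnames).
#' @param q_rho,q_sparcc FDR-adjusted p-value matrices.
#' @param kingdom Kingdom tag stored on the nodes.
#' @param corr_threshold Absolute correlation threshold (default 0.6).
#' @param alpha FDR level (default 0.05).
#' @return A `consensus_network`: list with `nodes` (data frame: `asv_id`,
#'   `kingdom`, `module` = NA until [detect_modules()]) and `edges` (data
#'   frame: `from`, `to`, `rho`, `sparcc_r`, `q_rho`, `q_sparcc`, `sign`).
#' @export
build_consensus_network <- function(rho, r_sparcc, q_rho, q_sparcc,
                                    kingdom = "prokaryote",
                                    corr_threshold = 0.6, alpha = 0.05) {
  stopifnot(identical(dim(rho), dim(r_sparcc)))
  ids <- colnames(rho)
  ut <- upper.tri(rho)
  idx <- which(ut &
                 !is.na(rho) & abs(rho) > corr_threshold &
                 !is.na(r_sparcc) & abs(r_sparcc) > corr_threshold &
                 !is.na(q_rho) & q_rho < alpha &
                 !is.na(q_sparcc) & q_sparcc < alpha,
               arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = rho[idx], sparcc_r = r_sparcc[idx],
                      q_rho = q_rho[idx], q_sparcc = q_sparcc[idx])
  disagree <- sign(edges$rho) != sign(edges$sparcc_r)
  if (any(disagree)) {
    warning(sum(disagree), " edge(s) dropped: Spearman/SparCC sign disagreement")
    edges <- edges[!disagree, , drop = FALSE]
  }
  edges$sign <- sign(edges$rho)
  nodes <- data.frame(asv_id = ids, kingdom = kingdom, module = NA_integer_)
  structure(list(nodes = nodes, edges = edges), class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d nodes, %d edges (%d positive), %s modules\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign > 0),
              if (all(is.na(x$nodes$module))) "no"
              else length(unique(stats::na.omit(x$nodes$module)))))
  invisible(x)
}

# igraph view of a consensus network, weighted by |rho|. Optionally keeps
# positive edges only (module detection: a negative edge joins taxa that
# exclude each other, and feeding its absolute weight to walktrap merges
# anti-correlated successional guilds into one module).
as_igraph <- function(network, nodes = network$nodes$asv_id,
                      positive_only = FALSE) {
  edges <- network$edges
  if (positive_only) edges <- edges[edges$sign > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes))
  igraph::E(g)$weight <- abs(edges$rho)
  igraph::E(g)$sign <- edges$sign
  g
}

#' Detect network modules with the walktrap algorithm
#'
#' Random-walk community detection cut at maximum modularity, run on the
#' positive-edge subgraph: negative consensus edges mark mutual exclusion,
#' and walking across them (even with absolute weights) merges
#' anti-correlated successional sub-communities into one module. Isolated
#' nodes get their own singleton modules. Modules are relabeled in
#' decreasing order of summed node abundance (module 1 = most abundant)
#' when `abundance` is supplied, else by size.
#'
#' @param network A `consensus_network`.
#' @param steps Walk length (default 4).
#' @param abundance Optional named per-ASV abundance used to order modules.
#' @param seed Integer seed (walktrap itself is deterministic; kept for
#'   interface uniformity).
#' @return The network with `nodes$module` filled in.
#' @export
detect_modules <- function(network, steps = 4, abundance = NULL, seed = 1L) {
  if (nrow(network$edges) == 0) {
    warning("empty edge set: every node is its own module")
    network$nodes$module <- seq_len(nrow(network$nodes))
    return(network)
  }
  g <- as_igraph(network, positive_only = TRUE)
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                             steps = steps)))
  memb <- memb[network$nodes$asv_id]
  size_stat <- if (is.null(abundance)) {
    tapply(rep(1, length(memb)), memb, sum)
  } else {
    tapply(abundance[network$nodes$asv_id], memb, sum)
  }
  relabel <- stats::setNames(seq_along(size_stat),
                             names(sort(size_stat, decreasing = TRUE)))
  network$nodes$module <- unname(relabel[as.character(memb)])
  network
}

#' Module completeness and abundance over time
#'
#' For every module M and sample t: completeness = fraction of M's nodes
#' detected (count > 0) at t; abundance = summed relative abundance of M's
#' nodes at t.
#'
#' @param network A `consensus_network` with modules assigned.
#' @param table A `count_table` containing every network node.
#' @return Tidy data frame: `module`, `sample_id`, `completeness`,
#'   `abundance`.
#' @export
module_dynamics <- function(network, table) {
  stopifnot(all(network$nodes$asv_id %in% asv_ids(table)))
  if (all(is.na(network$nodes$module))) stop("run detect_modules() first")
  rel <- rel_abundance(table)
  mods <- sort(unique(network$nodes$module))
  out <- lapply(mods, function(mod) {
    members <- network$nodes$asv_id[network$nodes$module == mod]
    sub <- rel[, members, drop = FALSE]
    data.frame(module = mod, sample_id = rownames(rel),
               completeness = rowMeans(sub > 0),
               abundance = rowSums(sub))
  })
  do.call(rbind, out)
}

#' Per-sample network properties
#'
#' For each sample, induces the subgraph of the consensus network on the
#' nodes detected (count > 0) in that sample and reports its edge density,
#' global (transitivity) clustering coefficient, and the weighted
#' modularity of a fresh walktrap run on the subgraph.
#'
#' @param network A `consensus_network`.
#' @param table A `count_table` containing every network node.
#' @param steps Walktrap walk length (default 4).
#' @param seed Integer seed.
#' @return Data frame: `sample_id`, `n_nodes`, `n_edges`, `density`,
#'   `clustering`, `modularity` (NA when fewer than 2 nodes are present).
#' @export
per_sample_network_stats <- function(network, table, steps = 4, seed = 1L) {
  g <- as_igraph(network)
  present <- table$counts[, network$nodes$asv_id, drop = FALSE] > 0
  rows <- lapply(seq_len(nrow(present)), function(i) {
    nodes <- colnames(present)[present[i, ]]
    if (length(nodes) < 2)
      return(data.frame(sample_id = rownames(present)[i],
                        n_nodes = length(nodes), n_edges = NA_integer_,
                        density = NA_real_, clustering = NA_real_,
                        modularity = NA_real_))
    sub <- igraph::induced_subgraph(g, nodes)
    ne <- igraph::ecount(sub)
    dens <- igraph::edge_density(sub)
    clus <- igraph::transitivity(sub, type = "global")
    modu <- if (ne > 0) {
      cl <- with_seed(derive_seed(seed, i),
                      igraph::cluster_walktrap(sub, steps = steps))
      igraph::modularity(sub, igraph::membership(cl),
                         weights = igraph::E(sub)$weight)
    } else NA_real_
    data.frame(sample_id = rownames(present)[i], n_nodes = length(nodes),
               n_edges = ne, density = dens,
               clustering = ifelse(is.nan(clus), 0, clus),
               modularity = modu)
  })
  do.call(rbind, rows)
}

#' Build the core inter-kingdom bipartite network
#'
#' Restricts each kingdom to its core ASVs (present in more than
#' `core_prevalence` of samples), computes cross-kingdom Spearman (each
#' kingdom closed separately) and SparCC (concatenated counts with a
#' kingdom-blocked Dirichlet draw) correlations, FDR-corrects the
#' cross-kingdom p-value pools separately, and keeps positive consensus
#' edges only.
#'
#' @param prok_table,euk_table `count_table`s over the same samples.
#' @param prok_network,euk_network Optional within-kingdom
#'   `consensus_network`s with modules, used to annotate nodes.
#' @param core_prevalence Core threshold (default 0.75, strict >).
#' @param corr_threshold Absolute correlation threshold (default 0.6).
#' @param alpha FDR level (default 0.05).
#' @param sparcc_control List of arguments passed to
#'   [sparcc_correlations()] (`n_inner`, `n_exclude_iter`,
#'   `exclude_threshold`, `n_boot`).
#' @param seed Integer seed.
#' @return A `bipartite_network`: list with `nodes` (asv_id, kingdom,
#'   module) and `edges` (prok, euk, rho, sparcc_r, q_rho, q_sparcc), plus
#'   `module_pair_counts`.
#' @export
build_bipartite_core_network <- function(prok_table, euk_table,
                                         prok_network = NULL,
                                         euk_network = NULL,
                                         core_prevalence = 0.75,
                                         corr_threshold = 0.6, alpha = 0.05,
                                         sparcc_control = list(), seed = 1L) {
  stopifnot(identical(sample_ids(prok_table), sample_ids(euk_table)))
  core <- function(tab) {
    keep <- colMeans(tab$counts > 0) > core_prevalence
    if (!any(keep)) stop("no core ASVs in ", tab$kingdom, " table")
    count_table(tab$counts[, keep, drop = FALSE], tab$kingdom)
  }
  pc <- core(prok_table)
  ec <- core(euk_table)
  sp <- spearman_correlations(pc, ec)
  q_rho <- matrix(bh_adjust(as.vector(sp$p)), nrow(sp$p), ncol(sp$p),
                  dimnames = dimnames(sp$p))
  sc_args <- c(list(table = pc, other = ec, seed = derive_seed(seed, 1)),
               sparcc_control)
  sc <- do.call(sparcc_correlations, sc_args)
  r_cross <- sc$r[asv_ids(pc), asv_ids(ec), drop = FALSE]
  p_cross <- sc$p[asv_ids(pc), asv_ids(ec), drop = FALSE]
  q_sparcc <- matrix(bh_adjust(as.vector(p_cross)), nrow(p_cross),
                     ncol(p_cross), dimnames = dimnames(p_cross))
  hit <- which(!is.na(sp$rho) & sp$rho > corr_threshold &
                 !is.na(r_cross) & r_cross > corr_threshold &
                 q_rho < alpha & q_sparcc < alpha, arr.ind = TRUE)
  edges <- data.frame(prok = asv_ids(pc)[hit[, 1]],
                      euk = asv_ids(ec)[hit[, 2]],
                      rho = sp$rho[hit], sparcc_r = r_cross[hit],
                      q_rho = q_rho[hit], q_sparcc = q_sparcc[hit])
  module_of <- function(net, ids) {
    if (is.null(net)) return(rep(NA_integer_, length(ids)))
    net$nodes$module[match(ids, net$nodes$asv_id)]
  }
  nodes <- rbind(
    data.frame(asv_id = asv_ids(pc), kingdom = "prokaryote",
               module = module_of(prok_network, asv_ids(pc))),
    data.frame(asv_id = asv_ids(ec), kingdom = "eukaryote",
               module = module_of(euk_network, asv_ids(ec))))
  pair_counts <- if (nrow(edges)) {
    mp <- module_of(prok_network, edges$prok)
    me <- module_of(euk_network, edges$euk)
    as.data.frame(table(prok_module = mp, euk_module = me),
                  responseName = "n_edges")
  } else data.frame(prok_module = integer(), euk_module = integer(),
                    n_edges = integer())
  structure(list(nodes = nodes, edges = edges,
                 module_pair_counts = pair_counts),
            class = "bipartite_network")
}

#' Write a consensus network as edge-list TSV
#' @param network A `consensus_network` or `bipartite_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a consensus network as GraphML
#' @param network A `consensus_network` with or without modules.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- as_igraph(network)
  if (!all(is.na(network$nodes$module)))
    igraph::V(g)$module <- network$nodes$module[
      match(igraph::V(g)$name, network$nodes$asv_id)]
  igraph::V(g)$kingdom <- network$nodes$kingdom[
    match(igraph::V(g)$name, network$nodes$asv_id)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
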