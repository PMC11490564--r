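#!/usr/bin/env Rscript
# Dual-method (Spearman + SparCC) consensus co-occurrence networks per
# kingdom, walktrap modules and their temporal completeness/abundance,
# per-time-point network properties, and the core inter-kingdom bipartite
# network.

library(gransucc)

prok <- load_dataset("results/dataset/prok_counts.tsv",
                     "results/dataset/prok_tree.nwk",
                     "results/dataset/env.csv", "prokaryote")
euk <- load_dataset("results/dataset/euk_counts.tsv",
                    "results/dataset/euk_tree.nwk",
                    "results/dataset/env.csv", "eukaryote")

nets <- list()
for (ds in list(prok, euk)) {
  k <- ds$table$kingdom
  filt <- filter_prevalence_abundance(ds$table)
  cat(sprintf("%s: %d of %d ASVs pass the 10%%/0.1%% filter\n",
              k, ncol(filt$counts), ncol(ds$table$counts)))
  sp <- spearman_correlations(filt)
  sc <- sparcc_correlations(filt, n_boot = 999, seed = 5)
  net <- build_consensus_network(sp$rho, sc$r, fdr_adjust_matrix(sp$p),
                                 fdr_adjust_matrix(sc$p), kingdom = k)
  net <- detect_modules(net, abundance = colSums(filt$counts) / sum(filt$counts))
  print(net)
  nets[[k]] <- net
  write_network_tsv(net, file.path("results", paste0(k, "_network_edges.tsv")))
  write.table(net$nodes, file.path("results", paste0(k, "_network_nodes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dyn <- module_dynamics(net, filt)
  write.table(dyn, file.path("results", paste0(k, "_module_dynamics.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  st <- per_sample_network_stats(net, filt, seed = 6)
  write.table(st, file.path("results", paste0(k, "_sample_network_stats.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

bn <- build_bipartite_core_network(prok$table, euk$table,
                                   nets$prokaryote, nets$eukaryote,
                                   sparcc_control = list(n_boot = 999),
                                   seed = 7)
write_network_tsv(bn, "results/bipartite_edges.tsv")
cat(sprintf("Bipartite core network: %d + %d core nodes, %d positive edges\n",
            sum(bn$nodes$kingdom == "prokaryote"),
            sum(bn$nodes$kingdom == "eukaryote"), nrow(bn$edges)))
print(bn$module_pair_counts[bn$module_pair_counts$n_edges > 0, ])
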