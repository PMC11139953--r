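# The default seeded synthetic cohort is used by several test files and by
# the acceptance checks; generate it once per session and memoise the full
# pipeline products alongside it.
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_cohort(sim_config(seed = 1L))
      catalog <- drop_par_y(sim$catalog)
      split <- split_by_biotype(catalog)
      expressed <- filter_expressed(sim$cohort, split$protein_coding, 0.05)
      st <- build_score_table(sim$cohort, expressed, tpm_cutoff = 0.05)
      sim$split <- split
      sim$expressed <- expressed
      sim$score_table <- st
      sim$call <- call_housekeeping(st, 0.2, "lt")
      cache <<- sim
    }
    cache
  }
})

truth_genes <- function(sim, class) {
  sim$truth$gene_id[sim$truth$class == class]
}
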