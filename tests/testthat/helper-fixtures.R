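# Fixtures are built in code; the brute-force oracles below recompute the
# f-statistics by naive per-SNP loops, independently of the package's
# vectorized implementations.

random_panel <- function(s = 5, pops = c("a", "b", "x", "i", "j"),
                         seed = 42, lo = 0.05, hi = 0.95) {
  set.seed(seed)
  frequency_panel(matrix(runif(s * length(pops), lo, hi), s,
                         dimnames = list(NULL, pops)))
}

bf_f2 <- function(panel, a, b) {
  s <- nrow(panel)
  acc <- 0
  for (k in seq_len(s)) acc <- acc + (panel[k, a] - panel[k, b])^2
  acc / s
}

bf_f3 <- function(panel, a, b, x) {
  s <- nrow(panel)
  acc <- 0
  for (k in seq_len(s)) {
    acc <- acc + (panel[k, x] - panel[k, a]) * (panel[k, x] - panel[k, b])
  }
  acc / s
}

bf_f4 <- function(panel, a, b, i, j) {
  s <- nrow(panel)
  acc <- 0
  for (k in seq_len(s)) {
    acc <- acc + (panel[k, a] - panel[k, b]) * (panel[k, i] - panel[k, j])
  }
  acc / s
}

# small shared-drift scenario used across tests: panel + exact hybrid,
# optionally noised; returns list(panel, config)
scenario2 <- function(s = 4000, n_aux = 8, alpha = 0.4, eps = 0,
                      seed = 7) {
  spec <- simulation_spec(s = s,
                          tree = default_drift_tree(n_aux = n_aux),
                          proportions = c(alpha, 1 - alpha), seed = seed,
                          noise_amplitude = eps)
  panel <- simulate_panel(spec)
  panel <- make_hybrid(panel, c("a", "b"), c(alpha, 1 - alpha))
  if (eps > 0) {
    panel <- add_post_admixture_noise(panel, c("a", "b", "x"), eps,
                                      seed = seed + 1)
  }
  aux <- setdiff(pop_names(panel), c("a", "b", "x"))
  list(panel = panel,
       config = admixture_config2("x", "a", "b", aux))
}

scenario3 <- function(s = 4000, n_aux = 9, props = c(0.2, 0.5, 0.3),
                      eps = 0, seed = 7) {
  tree <- default_drift_tree(n_aux = n_aux, donors = c("a", "b", "c"))
  spec <- simulation_spec(s = s, tree = tree, donors = c("a", "b", "c"),
                          proportions = props, seed = seed,
                          noise_amplitude = eps)
  panel <- simulate_panel(spec)
  panel <- make_hybrid(panel, c("a", "b", "c"), props)
  if (eps > 0) {
    panel <- add_post_admixture_noise(panel, c("a", "b", "c", "x"), eps,
                                      seed = seed + 1)
  }
  aux <- setdiff(pop_names(panel), c("a", "b", "c", "x"))
  list(panel = panel,
       config = admixture_config3("x", "a", "b", "c", aux))
}

write_panel_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
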