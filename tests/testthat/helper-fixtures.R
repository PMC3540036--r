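# Shared fixture builders.  Everything is generated in code; no data files.

# moderately specified motif (one dominant base per position), the kind of
# 8-bp site a typical yeast factor recognizes
fix_matrix <- function(w = 8, p = 0.8, cons = NULL, name = "fix") {
  if (is.null(cons)) cons <- rep_len(c(1, 3, 2, 4, 1, 2, 3, 4), w)
  pm <- matrix((1 - p) / 3, w, 4)
  for (i in seq_len(w)) pm[i, cons[i]] <- p
  freq_matrix(pm, name = name)
}

fix_consensus <- function(m) {
  paste(c("A", "C", "G", "T")[apply(m$probs, 1, which.max)], collapse = "")
}

# random strictly positive probability matrix
rand_matrix <- function(w, name = "rand") {
  x <- matrix(rexp(w * 4) + 0.05, w, 4)
  freq_matrix(x / rowSums(x), name = name)
}

rand_seq <- function(L, gc = 0.38) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
        collapse = "")
}

rand_seq_set <- function(n, L, gc = 0.38, prefix = "bgp") {
  setNames(vapply(seq_len(n), function(i) rand_seq(L, gc), character(1)),
           sprintf("%s_%03d", prefix, seq_len(n)))
}

# fast annealing schedule for test-scale fits
light_schedule <- function() anneal_schedule(t_init = 1, n_temps = 4,
                                             steps = 8)

# the synthetic study conditions used across tests: multisite signature at
# promoter scale
fix_model <- function(rho = 0.6, mu = 250, omega = 120, tau = 0.8,
                      lambda = 0.008, variant = "multisite", length = 1003,
                      w = 8, p = 0.8) {
  signature_model(fix_matrix(w = w, p = p), background_model(),
                  spatial_params(rho, mu, omega, tau, lambda),
                  variant = variant, length = length)
}

# small-instance model for enumeration oracles
tiny_model <- function(rho = 0.5, mu = 4, omega = 3, tau = 0.6,
                       lambda = 0.08, w = 3, variant = "multisite",
                       length = 12, p = 0.85) {
  signature_model(fix_matrix(w = w, p = p), background_model(),
                  spatial_params(rho, mu, omega, tau, lambda),
                  variant = variant, length = length)
}

write_fix_matrix_table <- function(m, path) {
  writeLines(apply(m$probs, 1, paste, collapse = " "), path)
  path
}

revcomp_test_helper <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

enumerate_seqs <- function(L) {
  g <- expand.grid(rep(list(c("A", "C", "G", "T")), L),
                   stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}
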