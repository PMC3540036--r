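#' Generate a synthetic training set
#'
#' Samples promoters from a signature model at variable lengths, returning
#' the ground-truth annotations alongside.  Variable lengths exercise the
#' length confound that the scramble control is designed to catch.
#'
#' @param model a [signature_model()].
#' @param n number of promoters.
#' @param lengths integer vector of promoter lengths (recycled to `n`),
#'   each at most 1003.
#' @param seed integer seed; the same seed gives byte-identical output.
#' @return list with `seqs`, `truth` (id, length, regulated, n_sites) and
#'   `sites` (id, start 0-based, strand).
#' @export
generate_training_set <- function(model, n, lengths = model$length,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lengths <- rep_len(as.integer(lengths), n)
  if (any(lengths > 1003)) stop("promoter lengths are capped at 1003 bp")
  if (any(lengths < model$matrix$width)) {
    stop("a promoter length is shorter than the motif")
  }
  seqs <- character(n)
  reg <- integer(n)
  nsite <- integer(n)
  site_rows <- vector("list", n)
  ids <- sprintf("prom_%04d", seq_len(n))
  for (i in seq_len(n)) {
    s <- sample_promoter(model, n = 1, length = lengths[i])
    seqs[i] <- s$seqs[[1]]
    reg[i] <- s$truth$regulated
    nsite[i] <- s$truth$n_sites
    site_rows[[i]] <- if (nrow(s$sites)) {
      data.frame(id = ids[i], start = s$sites$start,
                 strand = s$sites$strand)
    } else {
      NULL
    }
  }
  names(seqs) <- ids
  sites <- do.call(rbind, site_rows)
  if (is.null(sites)) {
    sites <- data.frame(id = character(0), start = integer(0),
                        strand = character(0))
  }
  list(seqs = seqs,
       truth = data.frame(id = ids, length = lengths, regulated = reg,
                          n_sites = nsite),
       sites = sites)
}

#' Generate a synthetic target-prediction benchmark
#'
#' Builds the inputs of an expression-recovery evaluation without any
#' external data: promoters sampled from the model (a fraction rho of them
#' carrying the signature), a per-ORF deletion expression change
#' concentrated on the true targets (`effect * regulated + noise`), and
#' surrogate ChIP binding p-values (Beta-skewed small for regulated
#' promoters, uniform otherwise).
#'
#' @param model a [signature_model()]; its rho sets the regulated
#'   fraction.
#' @param n_promoters number of promoters/ORFs.
#' @param effect expression change added to regulated ORFs (nonzero for a
#'   signal benchmark).
#' @param noise_sd standard deviation of the Gaussian expression noise.
#' @param seed integer seed.
#' @param length promoter length.
#' @param conditions number of surrogate ChIP conditions.
#' @return list with `promoters`, `truth`, `expression` (orf, change),
#'   `chip` (promoter + one p-value column per condition) and `params`
#'   (record of the generating settings).
#' @export
generate_benchmark <- function(model, n_promoters, effect, noise_sd,
                               seed = NULL, length = model$length,
                               conditions = 3) {
  if (!is.null(seed)) set.seed(seed)
  ts <- generate_training_set(model, n_promoters, lengths = length)
  reg <- ts$truth$regulated
  change <- effect * reg + rnorm(n_promoters, 0, noise_sd)
  chip <- matrix(runif(n_promoters * conditions), n_promoters, conditions)
  nreg <- sum(reg == 1)
  if (nreg > 0) {
    for (c in seq_len(conditions)) {
      chip[reg == 1, c] <- rbeta(nreg, 0.5, 10)
    }
  }
  chip_df <- data.frame(promoter = ts$truth$id)
  for (c in seq_len(conditions)) chip_df[[paste0("cond", c)]] <- chip[, c]
  list(promoters = ts$seqs, truth = ts$truth, sites = ts$sites,
       expression = data.frame(orf = ts$truth$id, change = change),
       chip = chip_df,
       params = list(n_promoters = n_promoters, effect = effect,
                     noise_sd = noise_sd, length = length,
                     rho = model$params$rho, noise_recorded = noise_sd))
}

#' Prepare a raw upstream region for modelling
#'
#' Trims the sequence from the 5' end to at most `max_len` bp (preserving
#' the TSS-proximal 3' end) and pads shorter sequences at the 5' end with
#' random GC-content fill.  Fill bases are flagged as masked (lowercase in
#' memory; written to a sidecar BED on disk) so that no site can initiate
#' within them.
#'
#' @param seq raw upstream sequence, 5'->3' with the TSS at the 3' end.
#' @param max_len length contract (default 1003).
#' @param gc GC content of the fill (default 0.38).
#' @return list with `seq` (exactly `max_len` bp, fill lowercase) and
#'   `fill` (data.frame start/end, 0-based half-open; zero rows when no
#'   fill was added).
#' @export
prepare_promoter <- function(seq, max_len = 1003, gc = 0.38) {
  if (!nzchar(seq)) stop("empty sequence")
  L <- nchar(seq)
  if (L >= max_len) {
    out <- substr(seq, L - max_len + 1, L)
    fill <- data.frame(start = integer(0), end = integer(0))
  } else {
    pad <- tolower(random_bg_seq(max_len - L, gc))
    out <- paste0(pad, seq)
    fill <- data.frame(start = 0L, end = max_len - L)
  }
  list(seq = out, fill = fill)
}
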