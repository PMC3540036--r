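#' Write promoters to FASTA (with a mask sidecar)
#'
#' Sequences are written uppercase; masked (lowercase) stretches are
#' recorded in a BED sidecar so the FASTA stays plain.
#'
#' @param seqs named character vector.
#' @param path FASTA output path.
#' @param mask_bed optional path for the mask BED (default: `path` with a
#'   `.mask.bed` suffix); written only if any sequence carries a mask.
#' @return the FASTA path, invisibly.
#' @export
write_promoters <- function(seqs, path, mask_bed = NULL) {
  if (is.null(mask_bed)) mask_bed <- paste0(path, ".mask.bed")
  xs <- Biostrings::DNAStringSet(toupper(seqs))
  names(xs) <- names(seqs)
  Biostrings::writeXStringSet(xs, path)
  rows <- lapply(names(seqs), function(id) {
    m <- encode_seq(seqs[[id]])$mask
    if (!any(m)) return(NULL)
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(chrom = id, start = starts[keep], end = ends[keep])
  })
  bed <- do.call(rbind, rows)
  if (!is.null(bed)) {
    write.table(bed, mask_bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read promoters from FASTA (re-applying a mask sidecar)
#'
#' @param path FASTA file.
#' @param mask_bed optional BED of masked intervals (chrom, start, end,
#'   0-based half-open); matching stretches are lowercased.
#' @return named character vector.
#' @export
read_promoters <- function(path, mask_bed = NULL) {
  xs <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(as.character(xs), names(xs))
  if (is.null(mask_bed) && file.exists(paste0(path, ".mask.bed"))) {
    mask_bed <- paste0(path, ".mask.bed")
  }
  if (!is.null(mask_bed) && file.exists(mask_bed)) {
    bed <- read.table(mask_bed, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end"))
    for (i in seq_len(nrow(bed))) {
      id <- as.character(bed$chrom[i])
      if (!id %in% names(seqs)) next
      s <- seqs[[id]]
      a <- bed$start[i] + 1
      b <- bed$end[i]
      substr(s, a, b) <- tolower(substr(s, a, b))
      seqs[[id]] <- s
    }
  }
  seqs
}

#' Serialize a signature model to YAML
#'
#' @param model a [signature_model()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path) {
  p <- model$params
  doc <- list(
    name = model$matrix$name,
    variant = model$variant,
    length = model$length,
    gc = model$bg$gc,
    params = list(rho = p$rho, mu = p$mu, omega = p$omega, tau = p$tau,
                  lambda = p$lambda, eta = p$eta),
    pseudocount = model$matrix$pseudocount,
    matrix = apply(model$matrix$probs, 1, function(r) as.list(unname(r)),
                   simplify = FALSE))
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

#' Read a signature model from YAML
#'
#' @param path a file written by [write_model()].
#' @return a [signature_model()].
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  probs <- do.call(rbind, lapply(doc$matrix, unlist))
  m <- freq_matrix(probs, pseudocount = 0, name = doc$name)
  m$pseudocount <- doc$pseudocount
  p <- doc$params
  signature_model(m, background_model(doc$gc),
                  spatial_params(p$rho, p$mu, p$omega, p$tau, p$lambda,
                                 p$eta),
                  variant = doc$variant, length = doc$length)
}

#' Write posterior site-start tracks as TSV
#'
#' @param posteriors named list of [forward_backward()] results.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_posterior_track <- function(posteriors, path) {
  rows <- lapply(names(posteriors), function(id) {
    tr <- posteriors[[id]]$site_start
    L <- ncol(tr)
    data.frame(promoter = id, position = rep(0:(L - 1), 2),
               strand = rep(c("+", "-"), each = L),
               site_start_posterior = c(tr[1, ], tr[2, ]))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Aggregates the package-wide defaults (all overridable where used):
#' 15 EM starts, training minimum of 20 promoters, GC 0.38, promoter
#' length cap 1003 bp, top-K cutoff 50, 5000 / 10000 resampling counts,
#' and the annealing/scramble settings.
#'
#' @return a named list.
#' @export
run_config <- function() {
  list(seed = 1L, variant = "multisite", starts = 15L, gc = 0.38,
       max_promoter_length = 1003L, training_minimum = 20L, K = 50L,
       eval_resamples = 5000L, comparison_reps = 10000L,
       anneal = unclass(anneal_schedule()),
       scramble = unclass(scramble_config()))
}
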