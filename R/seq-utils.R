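# Internal sequence plumbing.  Promoters are plain character strings, stored
# 5'->3' with the TSS at the right end.  Lowercase letters mark masked fill
# (real bases that emit background but cannot initiate or overlap a site);
# N marks unknown bases.

BASES <- c("A", "C", "G", "T")

# returns list(codes = integer 1..4 with 0 for N, mask = logical)
encode_seq <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  mask <- ch %in% c("a", "c", "g", "t", "n")
  up <- toupper(ch)
  codes <- match(up, BASES)
  codes[is.na(codes)] <- 0L
  list(codes = as.integer(codes), mask = mask)
}

decode_seq <- function(codes, mask = NULL) {
  ch <- c("N", BASES)[codes + 1L]
  if (!is.null(mask) && any(mask)) ch[mask] <- tolower(ch[mask])
  paste(ch, collapse = "")
}

revcomp <- function(seq) {
  ch <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            a = "t", c = "g", g = "c", t = "a", n = "n")
  out <- comp[ch]
  out[is.na(out)] <- "N"
  paste(out, collapse = "")
}

# named character vector in, list of encodings out
encode_set <- function(seqs) {
  lapply(seqs, encode_seq)
}

random_bg_seq <- function(L, gc = 0.38) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
}

auto_names <- function(x, prefix = "prom") {
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    names(x) <- sprintf("%s_%04d", prefix, seq_along(x))
  }
  x
}
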