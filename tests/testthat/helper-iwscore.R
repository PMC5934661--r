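# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths.

# lead eigenvector by plain power iteration (independent of eigen())
power_iteration <- function(a, tol = 1e-14, max_iter = 100000) {
  v <- rep(1 / sqrt(ncol(a)), ncol(a))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- a %*% v
    lambda_new <- sqrt(sum(w^2))
    w <- w / lambda_new
    if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) {
      v <- w
      lambda <- lambda_new
      break
    }
    v <- w
    lambda <- lambda_new
  }
  v <- as.numeric(v)
  if (sum(v) < 0) v <- -v
  list(vector = v, value = lambda)
}

random_psd <- function(k) {
  m <- matrix(rnorm(k * k), k)
  crossprod(m) / k
}

# AUC by brute force over all positive/negative pairs, ties counted 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# O(n*m) interval overlap: 1-based pos p vs 0-based half-open [s, e)
brute_overlap <- function(variants, regions) {
  lapply(seq_len(nrow(variants)), function(i) {
    hits <- character()
    for (j in seq_len(nrow(regions))) {
      if (variants$chrom[i] == regions$chrom[j] &&
          regions$start[j] <= variants$pos[i] - 1 &&
          variants$pos[i] - 1 < regions$end[j]) {
        hits <- c(hits, regions$label[j])
      }
    }
    hits
  })
}

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

# small complete score tibble with known columns
toy_scores <- function(n = 50, k = 3, seed = 1, systems = paste0("s", seq_len(k))) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      chrom = "chr1", pos = seq_len(n) * 10L,
      ref = "A", alt = "T"
    )
    for (s in systems) out[[s]] <- rnorm(n)
    out
  })
}
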