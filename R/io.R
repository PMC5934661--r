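KEY_COLS <- c("chrom", "pos", "ref", "alt")

#' Read query variants from VCF or TSV
#'
#' Variants are identified by `(chrom, pos, ref, alt)` with 1-based positions
#' (the VCF convention). Multi-allelic VCF records are split into one row per
#' alternate allele. Input order is preserved.
#'
#' @param path Path to a VCF 4.x file or a 4-column TSV
#'   (`chrom`, `pos`, `ref`, `alt`; a header row is optional).
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @param normalize_chrom If `TRUE`, strip a leading `"chr"` prefix from
#'   chromosome names. By default names are kept verbatim (`"chr1" != "1"`),
#'   since silent coercion hides join bugs.
#' @return A tibble with columns `chrom` (character), `pos` (integer),
#'   `ref`, `alt` (character).
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          normalize_chrom = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
  if (normalize_chrom) out$chrom <- sub("^chr", "", out$chrom)
  validate_variant_keys(out, path)
  out
}

read_variants_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(),
      ref = character(), alt = character()
    ))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # 1-row safety
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    abort(sprintf("malformed VCF record(s) at line(s): %s",
                  paste(which(is.na(pos)), collapse = ", ")))
  }
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  tibble::tibble(
    chrom = rep(fix[, "CHROM"], n_alt),
    pos = rep(pos, n_alt),
    ref = rep(fix[, "REF"], n_alt),
    alt = unlist(alts, use.names = FALSE)
  )
}

read_variants_tsv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- length(first) > 0 && grepl("^chrom\\b", first)
  df <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else KEY_COLS,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("parse error in %s at line %d: %s",
                  path, probs$row[1] + has_header, probs$expected[1]))
  }
  if (nrow(df) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(),
      ref = character(), alt = character()
    ))
  }
  tibble::as_tibble(df[KEY_COLS])
}

validate_variant_keys <- function(df, path = "<input>") {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad) > 0) {
    abort(sprintf("invalid position (pos < 1) in %s, record(s): %s",
                  path, paste(head(bad, 5), collapse = ", ")))
  }
  empty <- which(is.na(df$ref) | !nzchar(df$ref) | is.na(df$alt) | !nzchar(df$alt))
  if (length(empty) > 0) {
    abort(sprintf("empty ref/alt allele in %s, record(s): %s",
                  path, paste(head(empty, 5), collapse = ", ")))
  }
  invisible(df)
}

#' Read a variants-by-systems score table
#'
#' Reads a TSV with header `chrom, pos, ref, alt` followed by one numeric
#' column per scoring system. Cells encoded `NA`, `NaN` or empty are treated
#' as missing (scores for a variant are allowed to be absent for some
#' systems). Columns not in `systems` are dropped with a warning; the result's
#' system columns follow the order of `systems`.
#'
#' @param path Path to the TSV file.
#' @param systems Character vector of required system columns. Defaults to
#'   every non-key column present.
#' @return A tibble `chrom, pos, ref, alt, <systems...>` with `NA` for
#'   missing scores.
#' @export
read_score_table <- function(path, systems = NULL) {
  df <- readr::read_tsv(path, na = c("NA", "NaN", ""),
                        progress = FALSE, show_col_types = FALSE)
  missing_keys <- setdiff(KEY_COLS, names(df))
  if (length(missing_keys) > 0) {
    abort(sprintf("score table %s lacks key column(s): %s",
                  path, paste(missing_keys, collapse = ", ")))
  }
  if (is.null(systems)) systems <- setdiff(names(df), KEY_COLS)
  absent <- setdiff(systems, names(df))
  if (length(absent) > 0) {
    abort(sprintf("missing system(s): %s", paste(absent, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(KEY_COLS, systems))
  if (length(extra) > 0) {
    warn(sprintf("ignoring unrequested column(s): %s", paste(extra, collapse = ", ")))
  }
  for (s in systems) {
    if (!is.numeric(df[[s]])) {
      bad <- which(!is.na(df[[s]]))[1]
      abort(sprintf("non-numeric score in column '%s' (e.g. data row %d: '%s')",
                    s, bad, df[[s]][bad]))
    }
  }
  df$pos <- as.integer(df$pos)
  validate_variant_keys(df, path)
  tibble::as_tibble(df[c(KEY_COLS, systems)])
}

#' Read a BED file of labelled regions
#'
#' BED coordinates are 0-based, half-open `[start, end)`; they are kept that
#' way and converted only inside [overlap_regions()].
#'
#' @param path Path to a BED3+ file (tab-separated, no header). A 4th column,
#'   when present, is used as the region label; otherwise labels are
#'   `chrom:start-end`.
#' @return Tibble with columns `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE,
                        progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), label = character()))
  }
  out <- tibble::tibble(
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    label = if (ncol(df) >= 4) as.character(df[[4]])
            else sprintf("%s:%d-%d", df[[1]], df[[2]], df[[3]])
  )
  if (any(out$start >= out$end)) {
    abort("invalid BED interval: start must be < end")
  }
  out
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Annotate variants with overlapping regions
#'
#' A variant at 1-based position `p` overlaps a BED interval `[s, e)` iff
#' `s <= p - 1 < e`. All matching labels are reported.
#'
#' @param variants Data frame with at least `chrom` and `pos` (1-based).
#' @param regions Tibble as returned by [read_bed()].
#' @param normalize_chrom Strip a leading `"chr"` prefix from both inputs
#'   before matching. Default `FALSE` (verbatim matching).
#' @return The input tibble with a list-column `region_labels` (character
#'   vector per variant, empty when nothing overlaps).
#' @export
overlap_regions <- function(variants, regions, normalize_chrom = FALSE) {
  variants <- tibble::as_tibble(variants)
  vchrom <- variants$chrom
  rchrom <- regions$chrom
  if (normalize_chrom) {
    vchrom <- sub("^chr", "", vchrom)
    rchrom <- sub("^chr", "", rchrom)
  }
  labels <- rep(list(character()), nrow(variants))
  if (nrow(variants) > 0 && nrow(regions) > 0) {
    gv <- GenomicRanges::GRanges(vchrom, IRanges::IRanges(variants$pos, width = 1L))
    gr <- regions_to_granges(tibble::tibble(chrom = rchrom,
                                            start = regions$start, end = regions$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gv, gr))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    hit_labels <- split(regions$label[sh], factor(qh, levels = seq_len(nrow(variants))))
    labels <- lapply(hit_labels, as.character)
  }
  variants$region_labels <- unname(labels)
  variants
}

#' Write scored variants to TSV
#'
#' Column order is `chrom, pos, ref, alt, iw_score, p_value, rank`, then the
#' per-system rescaled values, then `imputed_systems` (semicolon-joined ids of
#' systems whose value was imputed) and, when present, `significant`.
#' Missing values are written as `NA`.
#'
#' @param scored Result of [score_variants()].
#' @param path Output path.
#' @return `scored`, invisibly.
#' @export
write_scored_tsv <- function(scored, path) {
  if (nrow(scored) == 0) abort("refusing to write an empty scored set")
  lead <- c(KEY_COLS, "iw_score", "p_value", "rank")
  sys_cols <- setdiff(names(scored), c(lead, "imputed_systems", "significant"))
  cols <- c(lead, sys_cols, intersect(c("imputed_systems", "significant"), names(scored)))
  readr::write_tsv(scored[cols], path, na = "NA", progress = FALSE)
  invisible(scored)
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Save / load a trained model as JSON
#'
#' All numeric parameters are serialized at 17 significant digits, so a
#' save–load round trip reproduces every double bit-exactly.
#'
#' @param model An `iw_model` from [iw_train()].
#' @param path Path of the JSON model file.
#' @return `save_iw_model()` returns `model` invisibly; `load_iw_model()`
#'   returns the reconstructed `iw_model`.
#' @export
save_iw_model <- function(model, path) {
  stopifnot(inherits(model, "iw_model"))
  pool <- model$reference_pool
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    workflow = model$workflow,
    transformed_input = model$transformed_input,
    p_floor = model$p_floor,
    seed = model$seed,
    n_train = model$n_train,
    systems = model$systems,
    rescale = model$rescale,
    weights = as.list(model$weights),
    lead_eigenvalue = model$lead_eigenvalue,
    null = list(
      family = model$null$family,
      shift = model$null$shift,
      meanlog = model$null$meanlog,
      sdlog = model$null$sdlog,
      train_mean = model$null$train_mean,
      train_sd = model$null$train_sd,
      sorted_scores = model$null$sorted_scores
    ),
    imputation = model$imputation,
    reference_pool = lapply(
      setNames(seq_len(ncol(pool)), colnames(pool)),
      function(j) pool[, j]
    ),
    reference_pool_digest = pool_digest(pool)
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           dataframe = "columns", null = "null", na = "null")
  writeLines(json, path)
  invisible(model)
}

pool_digest <- function(pool) {
  sprintf("%dx%d:%.17g", nrow(pool), ncol(pool),
          if (length(pool)) sum(pool) else 0)
}

#' @rdname save_iw_model
#' @export
load_iw_model <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(payload$schema_version) ||
      !identical(payload$schema_version, MODEL_SCHEMA_VERSION)) {
    abort(sprintf("unknown model schema_version '%s' (expected '%s')",
                  payload$schema_version %||% "<none>", MODEL_SCHEMA_VERSION))
  }
  pool_cols <- payload$reference_pool
  pool <- if (length(pool_cols) == 0) {
    matrix(numeric(), nrow = 0, ncol = 0)
  } else {
    do.call(cbind, lapply(pool_cols, as.numeric))
  }
  if (!is.null(pool) && length(pool_cols) > 0) colnames(pool) <- names(pool_cols)
  null <- payload$null
  null$sorted_scores <- as.numeric(null$sorted_scores)
  class(null) <- "iw_null"
  model <- list(
    workflow = payload$workflow,
    transformed_input = payload$transformed_input,
    p_floor = payload$p_floor,
    seed = payload$seed,
    n_train = payload$n_train,
    systems = tibble::as_tibble(payload$systems),
    rescale = tibble::as_tibble(payload$rescale),
    weights = unlist(payload$weights),
    lead_eigenvalue = payload$lead_eigenvalue,
    null = null,
    imputation = payload$imputation,
    reference_pool = pool
  )
  class(model) <- "iw_model"
  stopifnot(identical(pool_digest(pool), payload$reference_pool_digest))
  model
}

## extract the numeric system matrix from a score tibble
score_matrix <- function(scores, systems) {
  absent <- setdiff(systems, names(scores))
  if (length(absent) > 0) {
    abort(sprintf("missing system(s): %s", paste(absent, collapse = ", ")))
  }
  m <- as.matrix(scores[systems])
  storage.mode(m) <- "double"
  m
}
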