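#' The constituent noncoding scoring systems
#'
#' Registry of the eleven per-variant noncoding functional scoring systems the
#' integrative score is built from: CADD, DeepSEA, Eigen, Eigen-PC, FATHMM-MKL
#' (noncoding), fitCons, FunSeq2, the three GWAVA classifiers (region, TSS,
#' unmatched) and ReMM.
#'
#' Each system carries two pieces of metadata:
#' * `transform` — how raw values are mapped onto the integration scale.
#'   DeepSEA reports a functional-significance p-value in (0, 1], which is
#'   made comparable to the other (higher-is-more-functional) scores by a
#'   `-log2` transform; all other systems are used as-is (`identity`).
#' * `known_only` — `TRUE` for the three GWAVA classifiers, which only score
#'   known (catalogued) variants and are therefore excluded from the
#'   novel-variant workflows.
#'
#' @return A tibble with columns `system`, `transform`
#'   (`"identity"` or `"neg_log2_p"`) and `known_only` (logical).
#' @seealso [workflow_systems()] for the preset subsets.
#' @export
#' @examples
#' iw_systems()
iw_systems <- function() {
  tibble::tibble(
    system = c(
      "cadd", "deepsea", "eigen", "eigen_pc", "fathmm_mkl", "fitcons",
      "funseq2", "gwava_region", "gwava_tss", "gwava_unmatched", "remm"
    ),
    transform = c(
      "identity", "neg_log2_p", "identity", "identity", "identity", "identity",
      "identity", "identity", "identity", "identity", "identity"
    ),
    known_only = c(
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, TRUE, TRUE, TRUE, FALSE
    )
  )
}

#' Workflow presets: which systems feed the integrative score
#'
#' Four presets cover the two use cases (known vs novel variants), each with a
#' stricter variant dropping the weakest constituents:
#' * `K11` — all eleven systems (known variants).
#' * `K10` — `K11` minus fitCons.
#' * `N8`  — `K11` minus the three GWAVA classifiers, which cannot score novel
#'   variants.
#' * `N6`  — `N8` minus CADD and DeepSEA (novel somatic variants).
#'
#' @param workflow One of `"K11"`, `"K10"`, `"N8"`, `"N6"`.
#' @return Character vector of active system identifiers, in registry order.
#' @export
#' @examples
#' workflow_systems("N6")
workflow_systems <- function(workflow = c("K11", "K10", "N8", "N6")) {
  workflow <- match.arg(workflow)
  all <- iw_systems()
  gwava <- all$system[all$known_only]
  switch(workflow,
    K11 = all$system,
    K10 = setdiff(all$system, "fitcons"),
    N8  = setdiff(all$system, gwava),
    N6  = setdiff(all$system, c(gwava, "cadd", "deepsea"))
  )
}

#' System specifications for a workflow or custom system set
#'
#' @param workflow Preset id, or `NULL` when `systems` is given.
#' @param systems Optional character vector of custom system ids. Unregistered
#'   ids are accepted and treated as `identity`-transform, not known-only.
#' @return Tibble with columns `system`, `transform`, `known_only` restricted
#'   and ordered to the active set.
#' @keywords internal
system_specs <- function(workflow = "K11", systems = NULL) {
  reg <- iw_systems()
  ids <- if (is.null(systems)) workflow_systems(workflow) else systems
  known <- reg[match(ids, reg$system), ]
  known$system <- ids
  known$transform[is.na(known$transform)] <- "identity"
  known$known_only[is.na(known$known_only)] <- FALSE
  known
}
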