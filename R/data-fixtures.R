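# Bundled example summary tables: per-organ mean accuracy metrics for
# three abdominal auto-segmentation models (two sequence-specific, one
# multi-sequence) over the twelve organs-at-risk, and the corresponding
# per-model means split by image set. Used as worked examples and as
# regression fixtures for the aggregation arithmetic.

#' Example per-organ mean metrics for three segmentation models
#'
#' Mean values of the six accuracy metrics for each of the twelve
#' abdominal organs under three deep-learning auto-segmentation models
#' (\code{t1_model}, \code{t2_model}, \code{multi_seq}), in long format —
#' the shape consumed by [aggregateMetrics()] and [percentBestGood()].
#'
#' @return Data.frame with columns \code{organ}, \code{model}, \code{dsc},
#'   \code{mda_mm}, \code{hd95_mm}, \code{pvd_pct}, \code{sdsc},
#'   \code{rapl_mm_per_cc} (36 rows).
#' @examples
#' tab <- examplePerOrganMetrics()
#' aggregateMetrics(tab)$overall
#' @export
examplePerOrganMetrics <- function() {
    utils::read.csv(system.file("extdata", "per_organ_model_means.csv",
                                package = "contourQC"),
                    stringsAsFactors = FALSE)
}

#' Example per-model metric means split by image set
#'
#' Overall mean metrics of the sequence-specific models on their own image
#' sets and of the multi-sequence model on both sets; averaging the two
#' multi-sequence rows gives that model's global summary.
#'
#' @return Data.frame with columns \code{model}, \code{image_set} and the
#'   six metric columns (4 rows).
#' @export
exampleModelSequenceMeans <- function() {
    utils::read.csv(system.file("extdata", "model_sequence_means.csv",
                                package = "contourQC"),
                    stringsAsFactors = FALSE)
}
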