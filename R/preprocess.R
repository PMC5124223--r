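#' Beta values from methylated/unmethylated intensities
#'
#' `beta = M / (M + U + offset)` elementwise, with the conventional offset of
#' 100 stabilizing low-intensity probes. Cells with a missing intensity are
#' missing (`NA`) in the output.
#'
#' @param M,U non-negative intensity matrices (samples x CpGs), same shape.
#' @param offset positive stabilizing constant.
#' @return Beta matrix in `[0, 1]`, `NA` marking missing cells.
#' @examples
#' compute_beta(matrix(900), matrix(0))    # 0.9
#' @export
compute_beta <- function(M, U, offset = 100) {
  stopifnot(offset > 0)
  M <- as.matrix(M); U <- as.matrix(U)
  if (!identical(dim(M), dim(U))) stop("M and U must have the same shape")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE)) {
    stop("negative intensities")
  }
  beta <- M / (M + U + offset)
  beta[is.na(M) | is.na(U)] <- NA_real_
  beta
}

norm_chrom_ <- function(x) sub("^chr", "", as.character(x))

#' Probe-level quality-control filtering
#'
#' Removes control probes, probes on the X and Y chromosomes, and probes with
#' more than `max_missing` missing values, in that fixed precedence, so each
#' probe is counted under exactly one removal reason.
#'
#' @param m beta matrix (samples x CpGs, `NA` = missing).
#' @param ann annotation data frame with columns `cpg_id`, `chromosome`,
#'   `position`, `genes`, `is_control`; every matrix CpG must be annotated.
#' @param max_missing maximum tolerated missing fraction per probe.
#' @return List with `methylation` (filtered matrix) and `report`
#'   (`probes_removed` counts by reason plus input/output dimensions).
#' @export
filter_probes <- function(m, ann, max_missing = 0.10) {
  cpgs <- colnames(m)
  idx <- match(cpgs, ann$cpg_id)
  if (anyNA(idx)) {
    stop("unannotated CpG(s): ",
         paste(utils::head(cpgs[is.na(idx)], 5), collapse = ", "))
  }
  ann <- ann[idx, , drop = FALSE]
  chrom <- norm_chrom_(ann$chromosome)
  allowed <- c(as.character(1:22), "X", "Y")
  if (any(!chrom %in% allowed)) {
    stop("chromosome labels outside 1-22/X/Y: ",
         paste(unique(chrom[!chrom %in% allowed]), collapse = ", "))
  }
  miss <- colMeans(is.na(m))
  reason <- rep(NA_character_, ncol(m))
  reason[miss > max_missing] <- "missingness"
  reason[chrom == "Y"] <- "chrY"
  reason[chrom == "X"] <- "chrX"
  reason[as.logical(ann$is_control)] <- "control"
  keep <- is.na(reason)
  removed <- c(control = sum(reason == "control", na.rm = TRUE),
               chrX = sum(reason == "chrX", na.rm = TRUE),
               chrY = sum(reason == "chrY", na.rm = TRUE),
               missingness = sum(reason == "missingness", na.rm = TRUE))
  list(methylation = m[, keep, drop = FALSE],
       report = list(probes_removed = removed,
                     n_input = ncol(m), n_retained = sum(keep)))
}

#' Sample-level quality-control filtering
#'
#' Removes samples flagged as failed by the platform, samples violating the
#' detection-p rule, and samples whose reported and predicted sex disagree,
#' with that precedence. By default a *high* mean detection p-value (poor
#' signal) triggers removal; `detection_direction = "flag_low"` implements
#' the literal low-side reading instead.
#'
#' @param m beta matrix (samples x CpGs).
#' @param samples sample table with columns `illumina_failed`,
#'   `mean_detection_p`, `sex_reported`, `sex_predicted`.
#' @param detection_threshold mean detection p-value threshold (0.05).
#' @param detection_direction `"flag_high"` (default) removes samples with
#'   mean detection p above the threshold; `"flag_low"` removes below it.
#' @return List with `methylation`, `samples` (both filtered) and `report`
#'   (`samples_removed` counts by reason).
#' @export
filter_samples <- function(m, samples, detection_threshold = 0.05,
                           detection_direction = c("flag_high", "flag_low")) {
  detection_direction <- match.arg(detection_direction)
  need <- c("illumina_failed", "mean_detection_p", "sex_reported",
            "sex_predicted")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    stop("missing sample QC field(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(nrow(samples) == nrow(m))
  det_bad <- if (detection_direction == "flag_high") {
    samples$mean_detection_p > detection_threshold
  } else {
    samples$mean_detection_p < detection_threshold
  }
  reason <- rep(NA_character_, nrow(m))
  reason[samples$sex_reported != samples$sex_predicted] <- "sex_mismatch"
  reason[det_bad] <- "detection"
  reason[as.logical(samples$illumina_failed)] <- "failed"
  keep <- is.na(reason)
  removed <- c(failed = sum(reason == "failed", na.rm = TRUE),
               detection = sum(reason == "detection", na.rm = TRUE),
               sex_mismatch = sum(reason == "sex_mismatch", na.rm = TRUE))
  list(methylation = m[keep, , drop = FALSE],
       samples = samples[keep, , drop = FALSE],
       report = list(samples_removed = removed,
                     n_input = nrow(m), n_retained = sum(keep)))
}

# Per-CpG mean imputation at model-fit time (never stored back to the cohort).
impute_col_means_ <- function(m) {
  if (!anyNA(m)) return(m)
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0.5
  idx <- which(is.na(m))
  m[idx] <- mu[(idx - 1L) %/% nrow(m) + 1L]
  m
}
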