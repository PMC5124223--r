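#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q(i) = min_{j >= i} min(1, p(j) * m / j)`, returned in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order; `q >= p` elementwise.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

cell_fraction_names <- function() c("CD8T", "CD4T", "NK", "Bcell", "Mono",
                                    "Gran")

#' FDR-screened covariate selection
#'
#' Each candidate is tested for association with the exposure by ordinary
#' least squares (`exposure ~ candidate`), with k-level categorical candidates
#' dummy-encoded and judged by the joint F-test, so one two-sided p-value is
#' produced per candidate. p-values are BH-adjusted across candidates and
#' candidates with `q < q_threshold` are selected. The six cell-type
#' fractions are always carried as forced covariates; one of them
#' (`drop_fraction`, by default the granulocyte compartment) is dropped from
#' design matrices because the fractions sum to one and would otherwise be
#' collinear with the intercept.
#'
#' @param samples sample table containing `exposure`, the candidates and the
#'   cell fractions. Rows with a missing exposure or candidate value are
#'   dropped for that candidate's test.
#' @param candidates character vector of candidate column names.
#' @param q_threshold BH q-value inclusion threshold (0.1).
#' @param exposure name of the exposure column.
#' @param forced names of the forced cell-fraction columns.
#' @param drop_fraction forced column excluded from design matrices to keep
#'   them full rank (set `NULL` to keep all six and fail on rank deficiency).
#' @return Object of class `"covariate_selection"`: a list with `table`
#'   (candidate, p, q, selected), `selected`, `forced`, `drop_fraction`,
#'   `exposure`.
#' @export
select_covariates <- function(samples, candidates, q_threshold = 0.1,
                              exposure = "exposure",
                              forced = cell_fraction_names(),
                              drop_fraction = "Gran") {
  stopifnot(exposure %in% names(samples))
  y_all <- samples[[exposure]]
  if (length(unique(y_all[!is.na(y_all)])) < 2L) {
    stop("exposure has fewer than 2 distinct values")
  }
  missing_cand <- setdiff(candidates, names(samples))
  if (length(missing_cand)) {
    stop("candidate column(s) not found: ",
         paste(missing_cand, collapse = ", "))
  }
  p <- setNames(rep(NA_real_, length(candidates)), candidates)
  for (cand in candidates) {
    x <- samples[[cand]]
    ok <- !is.na(x) & !is.na(y_all)
    x <- x[ok]
    if (length(unique(x)) < 2L) {
      warning(sprintf("candidate '%s' is constant; association p undefined, excluded", cand))
      next
    }
    if (is.character(x)) x <- factor(x)
    fit <- lm(y_all[ok] ~ x)
    fs <- summary(fit)$fstatistic
    p[cand] <- pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  }
  tested <- !is.na(p)
  q <- setNames(rep(NA_real_, length(p)), names(p))
  q[tested] <- bh_adjust(p[tested])
  selected <- names(p)[tested & q < q_threshold]
  missing_forced <- setdiff(forced, names(samples))
  if (length(missing_forced)) {
    stop("forced cell-fraction column(s) not found: ",
         paste(missing_forced, collapse = ", "))
  }
  structure(list(table = data.frame(candidate = candidates,
                                    p_value = unname(p),
                                    q_value = unname(q),
                                    selected = candidates %in% selected,
                                    stringsAsFactors = FALSE),
                 selected = selected,
                 forced = forced,
                 drop_fraction = drop_fraction,
                 exposure = exposure,
                 q_threshold = q_threshold),
            class = "covariate_selection")
}

#' @export
print.covariate_selection <- function(x, ...) {
  cat(sprintf("covariate selection: %d candidate(s), selected: %s; forced: %s\n",
              nrow(x$table),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)",
              paste(x$forced, collapse = ", ")))
  invisible(x)
}

#' Design matrix implied by a covariate selection
#'
#' Intercept, selected covariates (categoricals dummy-encoded) and the forced
#' cell fractions minus the dropped compartment.
#'
#' @param samples sample table.
#' @param selection a [select_covariates()] result.
#' @return Numeric design matrix with `nrow(samples)` rows.
#' @export
build_design <- function(samples, selection) {
  stopifnot(inherits(selection, "covariate_selection"))
  forced <- setdiff(selection$forced, selection$drop_fraction)
  vars <- c(selection$selected, forced)
  df <- samples[, vars, drop = FALSE]
  if (anyNA(df)) {
    stop("missing values in design covariates; drop incomplete rows first")
  }
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  if (!ncol(df)) return(matrix(1, nrow(samples), 1,
                               dimnames = list(NULL, "(Intercept)")))
  model.matrix(reformulate(sprintf("`%s`", vars)), data = df)
}
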