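# Statistics linking simulated bilayer features to delivery performance:
# Pearson correlations (overall, amine-stratified, CPP>1 subset),
# stable-vs-unstable group comparisons, and the joined report table.

.cor_row <- function(feature, delivery, feature_name, stratum, subset_rule) {
  ok <- is.finite(feature) & is.finite(delivery)
  feature <- feature[ok]; delivery <- delivery[ok]
  n <- length(feature)
  if (n < 3L) {
    warning("stratum '", stratum, "' skipped: fewer than 3 paired observations")
    return(NULL)
  }
  if (stats::sd(feature) == 0 || stats::sd(delivery) == 0)
    stop("undefined-correlation error: zero variance in stratum '",
         stratum, "'")
  ct <- stats::cor.test(feature, delivery, method = "pearson")
  fit <- stats::lm.fit(cbind(1, feature), delivery)
  data.frame(feature_name = feature_name, stratum = stratum,
             subset_rule = subset_rule, n = n,
             pearson_r = unname(ct$estimate), p_value = ct$p.value,
             slope = fit$coefficients[2L], intercept = fit$coefficients[1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate a simulated feature with delivery performance
#'
#' Pearson correlation, two-sided p-value and least-squares line between a
#' per-formulation feature (e.g. mean CPP_V) and the standardized delivery
#' readout: overall, per stratum (e.g. per ionizable-lipid amine), and on
#' an optional subset. The subset rule \code{"cpp>1"} restricts to rows
#' whose feature value (a per-formulation mean CPP) exceeds 1; a predicate
#' function over the table may be supplied instead.
#'
#' @param table data frame with columns \code{feature}, \code{delivery}
#'   and optionally \code{stratum}.
#' @param by_stratum also report each stratum separately.
#' @param subset_rule \code{NULL}, the string \code{"cpp>1"}, or a
#'   function(table) returning a logical row mask.
#' @param feature_name label used in the output.
#' @return data frame of correlation rows (feature_name, stratum,
#'   subset_rule, n, pearson_r, p_value, slope, intercept).
#' @export
correlate_feature_delivery <- function(table, by_stratum = FALSE,
                                       subset_rule = NULL,
                                       feature_name = "feature") {
  stopifnot(all(c("feature", "delivery") %in% names(table)))
  out <- list(.cor_row(table$feature, table$delivery, feature_name,
                       "overall", "none"))
  if (by_stratum && "stratum" %in% names(table)) {
    for (s in unique(table$stratum)) {
      rows <- table$stratum == s
      out <- c(out, list(.cor_row(table$feature[rows], table$delivery[rows],
                                  feature_name, s, "none")))
    }
  }
  if (!is.null(subset_rule)) {
    if (is.function(subset_rule)) {
      mask <- subset_rule(table)
      label <- "predicate"
    } else if (identical(subset_rule, "cpp>1")) {
      mask <- table$feature > 1
      label <- "cpp>1"
    } else {
      stop("unknown subset rule: ", subset_rule)
    }
    out <- c(out, list(.cor_row(table$feature[mask], table$delivery[mask],
                                feature_name, "overall", label)))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Compare two groups of delivery readouts
#'
#' Rank-based comparison of delivery performance between two groups of
#' formulations (e.g. those forming stable versus unstable bilayers).
#' \code{rank_sum} is the two-sample Wilcoxon (Mann-Whitney) test;
#' \code{signed_rank} is the paired Wilcoxon test and requires equal
#' lengths. Ties are handled by midranks (normal approximation with
#' continuity correction when exact p-values are unavailable).
#'
#' @param values_a,values_b numeric vectors.
#' @param test \code{"rank_sum"} or \code{"signed_rank"}.
#' @param two_sided two-sided p-value (default) or greater-tail.
#' @return list of class \code{group_comparison}: test, statistic,
#'   p_value, n_a, n_b, two_sided.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("rank_sum", "signed_rank"),
                           two_sided = TRUE) {
  test <- match.arg(test)
  alt <- if (two_sided) "two.sided" else "greater"
  if (test == "signed_rank") {
    if (length(values_a) != length(values_b))
      stop("pairing error: signed-rank test requires equal-length samples")
    wt <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, paired = TRUE,
                         alternative = alt))
  } else {
    if (length(values_a) < 3L || length(values_b) < 3L)
      stop("rank-sum test requires at least 3 observations per group")
    wt <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, alternative = alt))
  }
  structure(list(test = test, statistic = unname(wt$statistic),
                 p_value = wt$p.value, n_a = length(values_a),
                 n_b = length(values_b), two_sided = two_sided),
            class = "group_comparison")
}

#' Join simulated features with standardized formulation records
#'
#' Builds the analysis table: one row per formulation x feature x charge
#' state with the feature mean, its dispersion (SEM for CPP_V, SD for
#' CPP_Rg), the stability label and the standardized delivery readout.
#' Formulations present in only one input are listed as unmatched.
#'
#' @param features data frame with columns \code{lnp_id},
#'   \code{feature_name}, \code{charge_state}, \code{mean},
#'   \code{dispersion}, \code{dispersion_type}, and optionally
#'   \code{stable}; one row per (lnp_id, feature_name, charge_state).
#' @param records standardized records (output \code{$records} of
#'   \code{\link{standardize_delivery}}).
#' @return list with \code{table} (joined data frame) and
#'   \code{unmatched} (lnp_ids present in features but not in records).
#' @export
build_report <- function(features, records) {
  need <- c("lnp_id", "feature_name", "charge_state", "mean", "dispersion",
            "dispersion_type")
  stopifnot(all(need %in% names(features)))
  stopifnot(all(c("lnp_id", "standardized_readout") %in% names(records)))
  key <- paste(features$lnp_id, features$feature_name,
               features$charge_state)
  if (anyDuplicated(key))
    stop("join error: duplicate (lnp_id, feature, charge_state) in features: ",
         key[duplicated(key)][1L])
  unmatched <- setdiff(unique(features$lnp_id), unique(records$lnp_id))
  keep <- features$lnp_id %in% records$lnp_id
  tab <- features[keep, , drop = FALSE]
  ridx <- match(tab$lnp_id, records$lnp_id)
  tab$standardized_readout <- records$standardized_readout[ridx]
  for (extra in c("ionizable_lipid_amine_id", "publication_id",
                  "delivery_context")) {
    if (extra %in% names(records)) tab[[extra]] <- records[[extra]][ridx]
  }
  list(table = tab, unmatched = unmatched)
}
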