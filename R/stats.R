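#' Pearson correlation between two membranes' permeation profiles
#'
#' Correlates paired mean cumulative amounts at matched sampling times,
#' typically Q through the synthetic membrane vs Q through excised skin.
#'
#' @param profileA,profileB Numeric vectors of equal length >= 3 (mean
#'   cumulative amounts at matched timepoints).
#' @param label Label carried into the result ("pooled" or a compound
#'   acronym).
#' @return List of class \code{correlation_result}: \code{label, r, r2, n}.
#' @export
pearson_profile_correlation <- function(profileA, profileB,
                                        label = "pooled") {
  if (length(profileA) != length(profileB))
    stop("profiles must have matched timepoints")
  if (length(profileA) < 3L) stop("need at least 3 paired points")
  if (stats::sd(profileA) == 0 || stats::sd(profileB) == 0)
    stop("undefined correlation: zero variance in a profile")
  r <- stats::cor(profileA, profileB)
  structure(list(label = label, r = r, r2 = r^2, n = length(profileA)),
            class = "correlation_result")
}

# Compact letter display by insert-and-absorb over the significance relation.
# signif: logical k x k matrix (TRUE = significantly different), means:
# group means used for the letter ordering (ascending).
cld_insert_absorb <- function(signif, means, labels) {
  k <- length(means)
  stopifnot(is.matrix(signif), nrow(signif) == k, ncol(signif) == k)
  ord <- order(means)                 # ascending means get letters first
  cols <- list(seq_len(k))            # start: one letter covering everyone
  pairs <- which(signif & upper.tri(signif), arr.ind = TRUE)
  if (nrow(pairs) > 0) for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    newcols <- list()
    for (col in cols) {
      if (i %in% col && j %in% col) {
        newcols <- c(newcols, list(setdiff(col, i)), list(setdiff(col, j)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    # absorb: drop any column whose members are a subset of another's
    keep <- rep(TRUE, length(newcols))
    for (a in seq_along(newcols)) {
      for (b in seq_along(newcols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newcols[[a]] %in% newcols[[b]]) &&
            !(all(newcols[[b]] %in% newcols[[a]]) && a < b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- newcols[keep]
  }
  # order letters by the lowest-mean member of each column
  colrank <- vapply(cols, function(col) min(match(col, ord)), numeric(1))
  cols <- cols[order(colrank)]
  letters_out <- rep("", k)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  }
  names(letters_out) <- labels
  letters_out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA, computes all-pairs Tukey honestly-significant-
#' difference adjusted p-values, and encodes the outcome as a compact letter
#' display (CLD): groups sharing a letter are not significantly different at
#' \code{alpha}. Letters run from 'a' upward ordered by ascending group
#' mean, so 'a' marks the lowest-responding group(s).
#'
#' @param values Numeric response vector.
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 observations each.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class \code{tukey_result}: \code{means} (named, input
#'   order), \code{letters} (named CLD strings), \code{p_adj} (named matrix
#'   of Tukey-adjusted p-values), \code{anova_F}, \code{anova_p},
#'   \code{alpha}.
#' @export
anova_tukey_cld <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("every group needs >= 2 observations; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  labs <- levels(groups)
  k <- length(labs)
  means <- tapply(values, groups, mean)
  ns <- as.numeric(sizes)
  df_err <- length(values) - k
  mse <- an["Residuals", "Mean Sq"]
  # Tukey HSD adjusted p-values from the studentized range distribution
  # (Tukey-Kramer standard error for unbalanced groups)
  pmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    p <- if (se == 0) {
      if (means[i] == means[j]) 1 else 0   # degenerate zero-variance case
    } else {
      stats::ptukey(abs(means[i] - means[j]) / se,
                    nmeans = k, df = df_err, lower.tail = FALSE)
    }
    pmat[i, j] <- pmat[j, i] <- p
  }
  diag(pmat) <- 1
  signif <- pmat < alpha
  diag(signif) <- FALSE
  letters_out <- cld_insert_absorb(signif, as.numeric(means), labs)
  structure(list(means = means, letters = letters_out, p_adj = pmat,
                 anova_F = an[1, "F value"], anova_p = an[1, "Pr(>F)"],
                 alpha = alpha), class = "tukey_result")
}

#' Tukey-adjusted comparisons against a control group
#'
#' Convenience extraction of each group's Tukey-adjusted p-value against a
#' designated control (the free-acid formulation in this pipeline). This is
#' a Dunnett-style reading of Tukey's all-pairs procedure, i.e. mildly
#' conservative, and is flagged as an approximation in reports.
#'
#' @param tukey A \code{tukey_result}.
#' @param control Control group label.
#' @return Named vector of adjusted p-values vs the control (control
#'   excluded).
#' @export
versus_control <- function(tukey, control) {
  stopifnot(inherits(tukey, "tukey_result"))
  if (!control %in% rownames(tukey$p_adj))
    stop("unknown control group: ", control)
  p <- tukey$p_adj[control, ]
  p[setdiff(names(p), control)]
}

#' Hierarchical clustering of penetration profiles
#'
#' Groups compounds by the shape and magnitude of their mean cumulative-
#' permeation curves: features (e.g. the concatenated mean profiles through
#' both membranes) are standardized per column, clustered agglomeratively
#' with Euclidean distance and Ward's criterion (\code{hclust} method
#' \code{"ward.D2"}), and the tree is cut at \code{k} groups. Cluster ids
#' are relabelled 1..k by descending mean terminal (24 h) cumulative mass so
#' cluster 1 is always the fastest-permeating group.
#'
#' @param features Numeric matrix, rows = compounds (rownames required),
#'   columns = profile features; no missing values.
#' @param k Number of clusters to cut (default 3).
#' @param q24 Optional per-compound terminal cumulative mass used for the
#'   cluster ordering; defaults to the row means of \code{features}.
#' @return List of class \code{cluster_result}: \code{assignment} (named
#'   integer vector), \code{merge_heights}, \code{hclust} (the tree),
#'   \code{k}, \code{dropped} (names of constant columns removed).
#' @export
cluster_penetration_profiles <- function(features, k = 3, q24 = NULL) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) stop("features needs rownames (compounds)")
  if (anyNA(features)) stop("features must not contain missing values")
  if (k < 1L || k > nrow(features)) stop("need 1 <= k <= number of compounds")
  if (is.null(q24)) q24 <- rowMeans(features)
  sds <- apply(features, 2, stats::sd)
  dropped <- colnames(features)[sds == 0]
  if (length(dropped) > 0L) {
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
    features <- features[, sds > 0, drop = FALSE]
  }
  if (ncol(features) == 0L) stop("no variable feature columns left")
  z <- scale(features)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # relabel clusters by descending mean terminal mass
  cl_mass <- tapply(q24, raw, mean)
  new_id <- rank(-cl_mass, ties.method = "first")
  assignment <- as.integer(new_id[as.character(raw)])
  names(assignment) <- rownames(features)
  structure(list(assignment = assignment, merge_heights = hc$height,
                 hclust = hc, k = k, dropped = dropped),
            class = "cluster_result")
}
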