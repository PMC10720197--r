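# Habitual-diet processing and microbiome association statistics: residual
# energy adjustment, ICC and exact signed-rank reproducibility tests,
# Spearman+BH association screens, and longitudinal dissimilarity dynamics.

#' Energy-adjust nutrient intakes by the residual method
#'
#' Each nutrient is regressed on total energy across observations by
#' ordinary least squares; the adjusted intake is the residual plus the
#' nutrient's grand mean, removing the confounding effect of total caloric
#' intake while keeping the original units.
#'
#' @param diet data frame with an energy column and nutrient columns.
#' @param nutrients names of the columns to adjust; defaults to all numeric
#'   columns except `energy_col`, `subject` and `timepoint`.
#' @param energy_col name of the energy column.
#' @return `diet` with the selected columns replaced by adjusted values.
#' @export
energy_adjust <- function(diet, nutrients = NULL, energy_col = "energy") {
  stopifnot(energy_col %in% names(diet))
  if (nrow(diet) < 3) stop("need at least 3 observations")
  if (is.null(nutrients)) {
    num <- vapply(diet, is.numeric, logical(1))
    nutrients <- setdiff(names(diet)[num],
                         c(energy_col, "subject", "timepoint"))
  }
  e <- diet[[energy_col]]
  if (var(e) == 0) {
    warning("energy is constant: slope set to 0, adjustment is the identity")
    return(diet)
  }
  for (nm in nutrients) {
    y <- diet[[nm]]
    fit <- lm(y ~ e)
    diet[[nm]] <- residuals(fit) + mean(y)
  }
  diet
}

#' Intraclass correlation coefficient for repeated administrations
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC(2,1) from
#' the standard mean-squares decomposition (the estimate may be negative).
#' `type = "ICC3"` gives the consistency form ICC(3,1), which ignores a
#' systematic shift between administrations.
#'
#' @param x numeric vector at administration 1, or an n x k matrix.
#' @param y numeric vector at administration 2 (when `x` is a vector).
#' @param type `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @return list with `icc`, `type` and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(x, y = NULL, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  m <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 subjects")
  grand <- mean(m)
  if (all(abs(m - grand) < 1e-12)) stop("zero total variance: ICC undefined")
  msr <- k * var(rowMeans(m))
  msc <- n * var(colMeans(m))
  sst <- sum((m - grand)^2)
  ssr <- (n - 1) * msr
  ssc <- (k - 1) * msc
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  val <- if (type == "ICC2")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  list(icc = val, type = type, msr = msr, msc = msc, mse = mse)
}

# exact two-sided signed-rank p via subset-sum DP over doubled midranks;
# handles ties exactly. W = sum of ranks of positive differences.
.signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1); f[1] <- 1 # f[s+1] = #subsets with doubled sum s
  for (r in r2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  probs <- f / sum(f)
  w2 <- round(2 * W)
  lower <- sum(probs[seq_len(w2 + 1)])
  upper <- sum(probs[(w2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Paired Wilcoxon signed-rank test with exact tied-rank distribution
#'
#' Zero differences are dropped; midranks are used for tied absolute
#' differences. For up to `exact_max` informative pairs the two-sided
#' p-value is computed from the exact permutation distribution of the
#' signed-rank statistic (equivalent to enumerating all sign assignments);
#' beyond that, the normal approximation with tie correction is used.
#'
#' @param x,y paired numeric vectors (or `y = NULL` and `x` the
#'   differences).
#' @param exact_max largest n for which the exact distribution is used.
#' @return list with `statistic` (W, sum of positive-difference ranks),
#'   `p.value`, `n_used`, `method`, `degenerate` (TRUE when every
#'   difference is zero, in which case p = 1).
#' @export
wilcoxon_signed_exact <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz))
    return(list(statistic = 0, p.value = 1, n_used = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(nz))
  W <- sum(r[nz > 0])
  n <- length(nz)
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4) # tie-corrected via midranks
    z <- (W - mu) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, p.value = p, n_used = n, method = method,
       degenerate = FALSE)
}

#' Per-variable reproducibility between two administrations
#'
#' Applies the paired signed-rank test ([wilcoxon_signed_exact()]) and the
#' intraclass correlation ([icc()]) to every shared numeric column of two
#' administration tables, the standard check that a questionnaire gives
#' consistent answers over time.
#'
#' @param time1,time2 data frames with identical numeric columns, one row
#'   per subject in the same order.
#' @return data frame with columns `variable`, `wilcoxon_p`, `icc`,
#'   `degenerate`.
#' @export
reproducibility_test <- function(time1, time2) {
  vars <- intersect(names(time1), names(time2))
  vars <- vars[vapply(time1[vars], is.numeric, logical(1))]
  vars <- setdiff(vars, c("subject", "timepoint"))
  rows <- lapply(vars, function(v) {
    w <- wilcoxon_signed_exact(time1[[v]], time2[[v]])
    ic <- tryCatch(icc(time1[[v]], time2[[v]])$icc, error = function(e) NA_real_)
    data.frame(variable = v, wilcoxon_p = w$p.value, icc = ic,
               degenerate = w$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman association screen with BH correction
#'
#' Spearman rank correlation (midranks for ties) between every
#' feature-variable pair, with Benjamini-Hochberg adjustment over the whole
#' screen. Constant columns are excluded with a message. Optionally both
#' sides are first residualized on covariates (partial-correlation mode).
#'
#' @param features samples x features numeric matrix/data frame (rownames =
#'   sample ids).
#' @param diet samples x variables numeric matrix/data frame.
#' @param fdr_max significance cutoff on the adjusted p-value.
#' @param partial_on optional covariate matrix (samples x covariates) to
#'   residualize on before correlating.
#' @return data frame of class `association_table` with columns `feature`,
#'   `variable`, `rho`, `p`, `fdr`, `significant`.
#' @export
association_screen <- function(features, diet, fdr_max = 0.05,
                               partial_on = NULL) {
  features <- as.data.frame(features)
  diet <- as.data.frame(diet)
  common <- intersect(rownames(features), rownames(diet))
  if (!length(common)) stop("no overlapping samples")
  features <- features[common, , drop = FALSE]
  diet <- diet[common, , drop = FALSE]
  drop_const <- function(df, what) {
    const <- vapply(df, function(v) var(v, na.rm = TRUE) == 0 ||
                      all(is.na(v)), logical(1))
    if (any(const))
      message("excluding constant ", what, " column(s): ",
              paste(names(df)[const], collapse = ", "))
    df[!const]
  }
  features <- drop_const(features, "feature")
  diet <- drop_const(diet, "diet")
  if (!is.null(partial_on)) {
    partial_on <- as.data.frame(partial_on)[common, , drop = FALSE]
    resid_on <- function(df) as.data.frame(lapply(df, function(v)
      residuals(lm(v ~ ., data = partial_on))))
    features <- resid_on(features); diet <- resid_on(diet)
  }
  rows <- list()
  for (f in names(features)) for (v in names(diet)) {
    ok <- stats::complete.cases(features[[f]], diet[[v]])
    if (sum(ok) < 4) {
      rows[[length(rows) + 1]] <- data.frame(feature = f, variable = v,
                                             rho = NA_real_, p = NA_real_)
      next
    }
    ct <- suppressWarnings(cor.test(features[[f]][ok], diet[[v]][ok],
                                    method = "spearman"))
    rows[[length(rows) + 1]] <- data.frame(feature = f, variable = v,
                                           rho = unname(ct$estimate),
                                           p = ct$p.value)
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_max
  class(out) <- c("association_table", class(out))
  out
}

#' Longitudinal dissimilarity dynamics
#'
#' Computes all pairwise Bray-Curtis dissimilarities among samples of one
#' (or two) communities, labels pairs intra- or inter-individual, builds
#' per-subject baseline trajectories (each later timepoint against the
#' subject's first), and tests (i) intra vs inter dissimilarity by rank-sum
#' and (ii) community A vs community B mean baseline dissimilarity by the
#' paired signed-rank test across matched subject-timepoints.
#'
#' @param profiles samples x taxa abundance matrix for the first community.
#' @param subject,timepoint vectors parallel to the rows of `profiles`.
#' @param profiles2 optional second community measured on the same samples.
#' @param labels community labels.
#' @return object of class `dynamics_analysis`: list with `dissimilarities`
#'   (pair table with `type` intra/inter), `trajectories` (subject,
#'   timepoint, dissimilarity to baseline, community), `intra_vs_inter`
#'   (p-value per community), `community_comparison` (paired p-value or
#'   NULL), `degenerate`.
#' @export
dynamics_analysis <- function(profiles, subject, timepoint, profiles2 = NULL,
                              labels = c("fungal", "bacterial")) {
  if (length(unique(subject)) < 2 || length(unique(timepoint)) < 2)
    stop("need at least 2 subjects and 2 timepoints")
  single <- table(subject)
  if (any(single == 1))
    warning("subject(s) with a single timepoint excluded from the intra set: ",
            paste(names(single)[single == 1], collapse = ", "))
  one_community <- function(mat, lab) {
    mat <- as.matrix(mat)
    n <- nrow(mat)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- apply(pairs, 1, function(ij) {
      v1 <- mat[ij[1], ]; v2 <- mat[ij[2], ]
      if (sum(v1) + sum(v2) == 0) return(NA_real_)
      1 - 2 * sum(pmin(v1, v2)) / (sum(v1) + sum(v2))
    })
    diss <- data.frame(i = pairs[, 1], j = pairs[, 2], value = d,
                       type = ifelse(subject[pairs[, 1]] == subject[pairs[, 2]],
                                     "intra", "inter"),
                       community = lab, stringsAsFactors = FALSE)
    base <- tapply(seq_len(n), subject, function(ix) ix[which.min(timepoint[ix])])
    traj <- do.call(rbind, lapply(unique(subject), function(s) {
      ix <- which(subject == s)
      b <- ix[which.min(timepoint[ix])]
      later <- ix[ix != b]
      if (!length(later)) return(NULL)
      data.frame(subject = s, timepoint = timepoint[later],
                 dissimilarity = vapply(later, function(k) {
                   v1 <- mat[b, ]; v2 <- mat[k, ]
                   1 - 2 * sum(pmin(v1, v2)) / (sum(v1) + sum(v2))
                 }, numeric(1)), community = lab, stringsAsFactors = FALSE)
    }))
    list(diss = diss, traj = traj)
  }
  c1 <- one_community(profiles, labels[1])
  res_d <- c1$diss; res_t <- c1$traj
  if (!is.null(profiles2)) {
    c2 <- one_community(profiles2, labels[2])
    res_d <- rbind(res_d, c2$diss)
    res_t <- rbind(res_t, c2$traj)
  }
  test_ii <- function(dd) {
    a <- dd$value[dd$type == "intra"]; b <- dd$value[dd$type == "inter"]
    if (!length(a) || !length(b) || (var(c(a, b)) == 0)) return(NA_real_)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  intra_vs_inter <- vapply(split(res_d, res_d$community), test_ii, numeric(1))
  community_comparison <- NULL
  degenerate <- all(res_d$value == 0, na.rm = TRUE)
  if (!is.null(profiles2)) {
    m <- merge(c1$traj, c2$traj, by = c("subject", "timepoint"))
    w <- wilcoxon_signed_exact(m$dissimilarity.x, m$dissimilarity.y)
    community_comparison <- list(p.value = w$p.value,
                                 mean_diff = mean(m$dissimilarity.x -
                                                    m$dissimilarity.y),
                                 degenerate = w$degenerate)
  }
  structure(list(dissimilarities = res_d, trajectories = res_t,
                 intra_vs_inter = intra_vs_inter,
                 community_comparison = community_comparison,
                 degenerate = degenerate),
            class = "dynamics_analysis")
}

#' @export
print.dynamics_analysis <- function(x, ...) {
  cat("Dynamics analysis:", nrow(x$dissimilarities), "pairwise dissimilarities (",
      sum(x$dissimilarities$type == "intra"), "intra,",
      sum(x$dissimilarities$type == "inter"), "inter )\n")
  if (!is.null(x$community_comparison))
    cat(sprintf("community comparison: paired signed-rank p = %.4g\n",
                x$community_comparison$p.value))
  invisible(x)
}
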