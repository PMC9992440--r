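# distance-based multivariate tests: PERMANOVA with a restricted nested
# permutation scheme, a two-factor sequential PERMANOVA, and a
# homogeneity-of-dispersion test. All significance is by permutation with
# the +1 rule: p = (count(F_perm >= F_obs) + 1) / (n_perm + 1).

permanova_result <- function(tab, scheme, n_perm, method, rank = NULL) {
  structure(list(aov_tab = tab, scheme = scheme, n_perm = n_perm,
                 method = method, rank = rank),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Permutational multivariate analysis of variance\n")
  cat("Permutation scheme:", x$scheme, "\n")
  if (x$method == "sampled")
    cat("Permutations:", x$n_perm, "(+1 rule)\n")
  else
    cat("Exhaustive enumeration of", x$n_perm, "assignments\n")
  tab <- x$aov_tab
  tab[] <- lapply(tab, function(c) if (is.numeric(c)) signif(c, 5) else c)
  print(tab, row.names = FALSE)
  invisible(x)
}

# squared-distance block sums between dates: B[a, b] = sum of d^2 over
# sample pairs (i in date a, j in date b)
date_block_sums <- function(D2, dates) {
  byrow <- rowsum(D2, dates)
  rowsum(t(byrow), dates)
}

# within-group sum of squares from date blocks for one assignment of dates
# to groups: SSW = sum_g (sum of B over the group's block) / (2 n_g)
ssw_from_blocks <- function(B, sizes, assign) {
  ssw <- 0
  for (lev in unique(assign)) {
    idx <- which(assign == lev)
    ssw <- ssw + sum(B[idx, idx]) / (2 * sum(sizes[idx]))
  }
  ssw
}

#' PERMANOVA with a restricted nested permutation scheme
#'
#' One-factor permutational MANOVA on Euclidean distances between response
#' rows (log-ratio coordinates), with samples nested within dates and
#' dates serving as the independent statistical replicates: permutations
#' reassign whole dates to sub-origins (preserving the observed group
#' sizes) and samples always move with their date. The pseudo-F is the
#' distance-based partitioning of the total sum of squares into
#' between-group and within-group components.
#'
#' @param response Numeric matrix (rows = samples), e.g. from
#'   [ilr_bivariate()].
#' @param dates Factor (or coercible) of the sampling date of each row.
#' @param groups_of_date Named vector mapping each date level to its group
#'   ("A"/"B" or any labels); alternatively a vector over rows that is
#'   constant within date.
#' @param n_perm Number of random permutations (ignored for
#'   `method = "exhaustive"`).
#' @param seed Optional integer seed for the permutation stream.
#' @param method `"sampled"` Monte-Carlo permutations (default) or
#'   `"exhaustive"` enumeration of all distinct date-label assignments
#'   (two groups only).
#' @return A `permanova_result` with the partition table, permutation
#'   p-value and scheme descriptor.
#' @export
permanova_nested <- function(response, dates, groups_of_date,
                             n_perm = 9999, seed = NULL,
                             method = c("sampled", "exhaustive")) {
  method <- match.arg(method)
  response <- as.matrix(response)
  dates <- factor(dates)
  n <- nrow(response)
  stopifnot(length(dates) == n)
  lev <- levels(dates)
  if (length(groups_of_date) == n && is.null(names(groups_of_date))) {
    # per-row group labels; must be constant within date
    g_by_date <- tapply(as.character(groups_of_date), dates,
                        function(x) unique(x))
    if (any(lengths(g_by_date) != 1))
      stop("groups_of_date varies within a date")
    g <- unlist(g_by_date)[lev]
  } else {
    if (!all(lev %in% names(groups_of_date)))
      stop("groups_of_date must name every date level")
    g <- as.character(groups_of_date[lev])
  }
  if (any(table(g) < 2))
    stop("insufficient replication: need >= 2 dates per sub-origin")

  D2 <- as.matrix(stats::dist(response))^2
  B <- date_block_sums(D2, dates)
  sizes <- as.vector(table(dates))
  a <- length(unique(g))
  ss_total <- sum(D2) / (2 * n)
  ss_within <- ssw_from_blocks(B, sizes, g)
  ss_between <- max(ss_total - ss_within, 0)
  df_b <- a - 1
  df_w <- n - a
  f_stat <- function(ssb, ssw) {
    if (ssb < 1e-12) return(0)
    (ssb / df_b) / (ssw / df_w)
  }
  f_obs <- f_stat(ss_between, ss_within)

  if (!is.null(seed)) set.seed(as.integer(seed))
  if (method == "exhaustive") {
    if (a != 2) stop("exhaustive enumeration supports two groups only")
    g1 <- unique(g)[1]
    n1 <- sum(g == g1)
    picks <- utils::combn(length(lev), n1)
    f_all <- apply(picks, 2, function(ix) {
      asg <- rep(unique(g)[2], length(lev))
      asg[ix] <- g1
      ssw <- ssw_from_blocks(B, sizes, asg)
      f_stat(max(ss_total - ssw, 0), ssw)
    })
    n_assign <- ncol(picks)
    p <- sum(f_all >= f_obs - 1e-12) / n_assign
    rank <- sum(f_all > f_obs + 1e-12) + 1
    n_perm_out <- n_assign
  } else {
    L <- length(lev)
    perm_lab <- t(vapply(seq_len(n_perm), function(i) sample(g), g))
    ssw_perm <- numeric(n_perm)
    for (levg in unique(g)) {
      M <- (perm_lab == levg) * 1
      quad <- rowSums((M %*% B) * M)
      ng <- as.vector(M %*% sizes)
      ssw_perm <- ssw_perm + quad / (2 * ng)
    }
    ssb_perm <- pmax(ss_total - ssw_perm, 0)
    f_perm <- ifelse(ssb_perm < 1e-12, 0,
                     (ssb_perm / df_b) / (ssw_perm / df_w))
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    rank <- sum(f_perm > f_obs + 1e-12) + 1
    n_perm_out <- n_perm
  }

  tab <- data.frame(
    term = c("suborigin", "Residuals", "Total"),
    Df = c(df_b, df_w, n - 1),
    SumOfSqs = c(ss_between, ss_within, ss_total),
    MeanSqs = c(ss_between / df_b, ss_within / df_w, NA),
    F.Model = c(f_obs, NA, NA),
    p = c(p, NA, NA))
  permanova_result(
    tab,
    scheme = "nested: whole dates permuted between sub-origins, samples fixed within dates",
    n_perm = n_perm_out, method = method, rank = rank)
}

#' Homogeneity of multivariate dispersion
#'
#' Tests whether groups differ in their spread around their own centroids:
#' the response rows are embedded by principal-coordinate analysis of their
#' Euclidean distance matrix, each point's distance to its own-group
#' centroid is computed, and a one-way F statistic on those distances is
#' assessed by freely permuting group labels.
#'
#' @param response Numeric matrix (rows = samples).
#' @param groups Factor of group membership per row (>= 2 members each).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return A `dispersion_result` with per-group mean distances, `F` and the
#'   permutation `p`.
#' @export
dispersion_homogeneity <- function(response, groups, n_perm = 999,
                                   seed = NULL) {
  response <- as.matrix(response)
  groups <- factor(groups)
  n <- nrow(response)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 members each")
  D <- stats::dist(response)
  pco <- stats::cmdscale(D, k = min(n - 1, ncol(response) + 1), eig = TRUE)
  keep <- pco$eig > max(pco$eig) * 1e-10
  pts <- pco$points[, seq_len(sum(keep[seq_len(ncol(pco$points))])), drop = FALSE]
  cent <- rowsum(pts, groups) / as.vector(table(groups))
  d <- sqrt(rowSums((pts - cent[groups, , drop = FALSE])^2))

  f_of <- function(dd, gg) {
    m <- tapply(dd, gg, mean)
    nn <- table(gg)
    ssb <- sum(nn * (m - mean(dd))^2)
    ssw <- sum((dd - m[gg])^2)
    if (ssb < 1e-14) return(0)
    (ssb / (nlevels(gg) - 1)) / (ssw / (n - nlevels(gg)))
  }
  f_obs <- f_of(d, groups)
  if (!is.null(seed)) set.seed(as.integer(seed))
  f_perm <- vapply(seq_len(n_perm),
                   function(i) f_of(d[sample.int(n)], groups), 0)
  p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(
    group_means = tapply(d, groups, mean),
    distances = d, groups = groups,
    F = f_obs, p = p, n_perm = n_perm),
    class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat("Homogeneity of multivariate dispersion\n")
  cat("Mean distance to group centroid:\n")
  print(signif(x$group_means, 4))
  cat(sprintf("F = %.4g, permutation p = %.4g (%d permutations)\n",
              x$F, x$p, x$n_perm))
  invisible(x)
}

hat_mat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Two-factor PERMANOVA for environmental conditions
#'
#' Sequential (Type I) distance-based partitioning of a bivariate
#' (SST, sqrt-chlorophyll) response into time-period, sub-origin and
#' interaction terms, with free row permutations and the +1 rule per term.
#' Columns are z-standardized by default since degrees Celsius and
#' mg m^-3 are incommensurable under Euclidean distance.
#'
#' @param records Data frame from [extract_env_records()] with columns
#'   `period`, `suborigin`, `sst_mean`, `chl_mean`.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param standardize z-score each response column (default `TRUE`).
#' @param sqrt_chl Square-root transform chlorophyll first (default
#'   `TRUE`).
#' @return A `permanova_result` with terms `period`, `suborigin`,
#'   `period:suborigin`, residual and total.
#' @export
env_permanova <- function(records, n_perm = 9999, seed = NULL,
                          standardize = TRUE, sqrt_chl = TRUE) {
  keep <- stats::complete.cases(records[, c("sst_mean", "chl_mean")])
  if (!all(keep)) {
    warning(sum(!keep), " record(s) with missing environmental data dropped")
    records <- records[keep, , drop = FALSE]
  }
  f1 <- factor(records$period)
  f2 <- factor(records$suborigin)
  if (nlevels(f1) < 2 || nlevels(f2) < 2 || any(table(f1, f2) == 0))
    stop("design error: every period x sub-origin cell must be non-empty")
  chl <- if (sqrt_chl) sqrt(records$chl_mean) else records$chl_mean
  Y <- cbind(sst = records$sst_mean, chl = chl)
  if (standardize) Y <- scale(Y)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  G <- tcrossprod(Yc)

  H0 <- matrix(1 / n, n, n)
  H1 <- hat_mat(stats::model.matrix(~f1))
  H12 <- hat_mat(stats::model.matrix(~f1 + f2))
  H123 <- hat_mat(stats::model.matrix(~f1 * f2))
  P <- list(period = H1 - H0, suborigin = H12 - H1,
            `period:suborigin` = H123 - H12)
  P_res <- diag(n) - H123
  df <- c(nlevels(f1) - 1, nlevels(f2) - 1,
          (nlevels(f1) - 1) * (nlevels(f2) - 1))
  df_res <- n - nlevels(f1) * nlevels(f2)

  ss <- vapply(P, function(Pk) sum(Pk * G), 0)
  ss_res <- sum(P_res * G)
  ss_tot <- sum(diag(G))
  f_obs <- (ss / df) / (ss_res / df_res)

  if (!is.null(seed)) set.seed(as.integer(seed))
  exceed <- numeric(3)
  for (b in seq_len(n_perm)) {
    pi <- sample.int(n)
    Gp <- G[pi, pi]
    ssp <- vapply(P, function(Pk) sum(Pk * Gp), 0)
    ssp_res <- sum(P_res * Gp)
    fp <- (ssp / df) / (ssp_res / df_res)
    exceed <- exceed + (fp >= f_obs - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)

  tab <- data.frame(
    term = c(names(P), "Residuals", "Total"),
    Df = c(df, df_res, n - 1),
    SumOfSqs = c(ss, ss_res, ss_tot),
    MeanSqs = c(ss / df, ss_res / df_res, NA),
    F.Model = c(f_obs, NA, NA),
    p = c(p, NA, NA))
  permanova_result(tab, scheme = "free row permutation, sequential SS",
                   n_perm = n_perm, method = "sampled")
}
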