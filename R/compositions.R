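# three-part compositional data: relative abundance, aggregation,
# log-ratio transform, ternary coordinates

#' Volumes to relative abundance
#'
#' Converts morphotype displacement volumes to a composition
#' (volume of morphotype / total volume of the sample).
#'
#' @param volumes Numeric vector of 3 volumes, or a matrix/data frame with
#'   3 columns in the order (SNI, SNVIII, SFIII).
#' @return Composition(s) of the same shape, rows summing to 1.
#' @export
to_relative_abundance <- function(volumes) {
  if (is.data.frame(volumes)) volumes <- as.matrix(volumes)
  if (is.null(dim(volumes))) {
    tot <- sum(volumes)
    if (tot <= 0) stop("total volume must be > 0: composition undefined")
    return(volumes / tot)
  }
  tot <- rowSums(volumes)
  if (any(tot <= 0)) stop("total volume must be > 0: composition undefined")
  sweep(volumes, 1, tot, "/")
}

# pull the three volume columns from a sample table
sample_volumes <- function(samples) {
  as.matrix(samples[, c("vol_sni_ml", "vol_snviii_ml", "vol_sfiii_ml")])
}

#' Two-stage aggregation of sample compositions
#'
#' Averages compositional data first by date (arithmetic mean of the
#' sample compositions collected that date) and then by month (arithmetic
#' mean of the date compositions), re-normalizing at each stage so every
#' date contributes equally to its month regardless of how many clumps it
#' holds.
#'
#' @param samples Sample data frame with columns `date`, `vol_sni_ml`,
#'   `vol_snviii_ml`, `vol_sfiii_ml`.
#' @return Data frame with `month` (`"YYYY-MM"`), `p_sni`, `p_snviii`,
#'   `p_sfiii`, `n_dates`.
#' @export
aggregate_date_then_month <- function(samples) {
  stopifnot(nrow(samples) > 0)
  comp <- to_relative_abundance(sample_volumes(samples))
  date <- as.factor(as.character(samples$date))
  by_date <- rowsum(comp, date) / as.vector(table(date))
  by_date <- by_date / rowSums(by_date)
  month <- as.factor(format(as.Date(rownames(by_date)), "%Y-%m"))
  by_month <- rowsum(by_date, month) / as.vector(table(month))
  by_month <- by_month / rowSums(by_month)
  data.frame(month = rownames(by_month),
             p_sni = by_month[, 1], p_snviii = by_month[, 2],
             p_sfiii = by_month[, 3],
             n_dates = as.integer(table(month)),
             row.names = NULL)
}

#' Isometric log-ratio transform to bivariate coordinates
#'
#' Maps three-part compositions to two unconstrained real coordinates,
#' removing the unit-sum dependence among the three proportions:
#' `z1 = (1/sqrt(2)) ln(p1/p2)`,
#' `z2 = sqrt(2/3) ln(sqrt(p1 p2) / p3)`.
#' Zeros are first replaced multiplicatively: zero parts get
#' `zero_replacement` and the remaining parts are scaled down to keep the
#' unit sum.
#'
#' @param comp Composition vector (length 3) or matrix with 3 columns.
#' @param zero_replacement Replacement proportion for zero parts.
#' @return Matrix with columns `z1`, `z2`.
#' @export
ilr_bivariate <- function(comp, zero_replacement = 0.005) {
  if (is.data.frame(comp)) comp <- as.matrix(comp)
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
  stopifnot(ncol(comp) == 3, all(comp >= 0),
            all(abs(rowSums(comp) - 1) < 1e-6))
  zero <- comp == 0
  if (any(zero)) {
    n0 <- rowSums(zero)
    scl <- 1 - n0 * zero_replacement
    comp <- sweep(comp, 1, scl, "*")
    comp[zero] <- zero_replacement
  }
  z1 <- (1 / sqrt(2)) * log(comp[, 1] / comp[, 2])
  z2 <- sqrt(2 / 3) * log(sqrt(comp[, 1] * comp[, 2]) / comp[, 3])
  cbind(z1 = z1, z2 = z2)
}

#' Inverse of the bivariate isometric log-ratio transform
#'
#' @param z Matrix with columns `z1`, `z2` (or a length-2 vector).
#' @return Matrix of three-part compositions (rows sum to 1).
#' @export
ilr_inverse <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  l1 <- z[, 1] / sqrt(2) + z[, 2] / sqrt(6)
  l2 <- -z[, 1] / sqrt(2) + z[, 2] / sqrt(6)
  l3 <- -2 * z[, 2] / sqrt(6)
  e <- cbind(exp(l1), exp(l2), exp(l3))
  e / rowSums(e)
}

#' Barycentric to Cartesian ternary-plot coordinates
#'
#' Vertex order (p1, p2, p3) = (SNI, SNVIII, SFIII): SNI at the origin,
#' SNVIII at (1, 0), SFIII at the apex (1/2, sqrt(3)/2); the triangle is
#' equilateral with side 1.
#'
#' @param comp Composition vector or matrix with 3 columns.
#' @return Matrix with plot columns `x`, `y`.
#' @export
ternary_coords <- function(comp) {
  if (is.data.frame(comp)) comp <- as.matrix(comp)
  if (is.null(dim(comp))) comp <- matrix(comp, nrow = 1)
  cbind(x = comp[, 2] + comp[, 3] / 2,
        y = sqrt(3) / 2 * comp[, 3])
}

#' Ternary scatter plot of three-part compositions
#'
#' Base-graphics ternary diagram with the (SNI, SNVIII, SFIII) vertex
#' convention of [ternary_coords()].
#'
#' @param comp Composition matrix (3 columns).
#' @param group Optional factor for point colours.
#' @param labels Vertex labels.
#' @param ... Passed to [graphics::points()].
#' @return Invisibly, the plotted (x, y) coordinates.
#' @export
plot_ternary <- function(comp, group = NULL,
                         labels = c("SNI", "SNVIII", "SFIII"), ...) {
  xy <- ternary_coords(comp)
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.08, 0.95),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0, 0))
  graphics::lines(tri)
  graphics::text(c(0, 1, 0.5), c(-0.05, -0.05, sqrt(3) / 2 + 0.05), labels)
  col <- if (is.null(group)) "black" else as.integer(as.factor(group)) + 1
  graphics::points(xy, col = col, pch = 19, ...)
  invisible(xy)
}
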