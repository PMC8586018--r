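# Gridded utilization distributions on a common global lattice, pairwise
# Bhattacharyya overlap / segregation indices, isopleths, colony-level UDs
# and the colony representativeness bootstrap.
#
# Every UD lives on one global lattice (cell indices i = floor(x / cell))
# anchored at the projection origin, so pairwise comparisons align cells
# exactly and never interpolate.

#' Construct a utilization distribution
#'
#' @param mass matrix of cell masses; rows index x-cells, columns y-cells.
#' @param i0,j0 lattice indices of `mass[1, 1]`: the cell covering
#'   `[i0 * cell, (i0 + 1) * cell)` etc.
#' @param cell cell size (m), default 500.
#' @return object of class `"ud"`. Masses must be non-negative and sum to 1
#'   (within 1e-9).
#' @export
ud_new <- function(mass, i0, j0, cell = 500) {
  mass <- as.matrix(mass)
  if (any(mass < 0)) stop("UD masses must be non-negative")
  if (abs(sum(mass) - 1) > 1e-9) stop("UD masses must sum to 1")
  structure(list(mass = mass, i0 = as.integer(i0), j0 = as.integer(j0),
                 cell = cell), class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat(sprintf("<ud: %d x %d cells of %g m, origin cell (%d, %d)>\n",
              nrow(x$mass), ncol(x$mass), x$cell, x$i0, x$j0))
  invisible(x)
}

# place two UDs on their union lattice window; returns list of two matrices
.union_grids <- function(ud1, ud2) {
  if (ud1$cell != ud2$cell) stop("UDs are on different cell sizes")
  i0 <- min(ud1$i0, ud2$i0)
  j0 <- min(ud1$j0, ud2$j0)
  i1 <- max(ud1$i0 + nrow(ud1$mass), ud2$i0 + nrow(ud2$mass)) - 1L
  j1 <- max(ud1$j0 + ncol(ud1$mass), ud2$j0 + ncol(ud2$mass)) - 1L
  put <- function(ud) {
    m <- matrix(0, i1 - i0 + 1L, j1 - j0 + 1L)
    ri <- (ud$i0 - i0 + 1L):(ud$i0 - i0 + nrow(ud$mass))
    rj <- (ud$j0 - j0 + 1L):(ud$j0 - j0 + ncol(ud$mass))
    m[ri, rj] <- ud$mass
    m
  }
  list(put(ud1), put(ud2))
}

#' Bhattacharyya coefficient and segregation index of two UDs
#'
#' `BA = sum_cells sqrt(p * q)` over the union lattice window; the
#' segregation index is `SI = 1 - BA`, from 0 (complete overlap) to 1 (full
#' segregation).
#'
#' @param ud1,ud2 `"ud"` objects on the same lattice (cell size).
#' @return list with `ba` and `si`.
#' @export
bhattacharyya <- function(ud1, ud2) {
  for (u in list(ud1, ud2)) {
    if (abs(sum(u$mass) - 1) > 1e-6) stop("UD is not normalized")
  }
  g <- .union_grids(ud1, ud2)
  ba <- sum(sqrt(g[[1]] * g[[2]]))
  ba <- min(max(ba, 0), 1)
  list(ba = ba, si = 1 - ba)
}

#' Pairwise segregation matrix among individuals
#'
#' Symmetric matrix of segregation indices `SI = 1 - BA` over all pairs of
#' individual UDs, with the colony label of each individual attached.
#'
#' @param uds named list of `"ud"` objects (>= 2), names = individual ids.
#' @param colony character vector of colony labels, same length/order.
#' @return matrix of class `"segregation_matrix"` with zero diagonal and a
#'   `colony` attribute.
#' @export
segregation_matrix <- function(uds, colony) {
  n <- length(uds)
  if (n < 2) stop("need >= 2 individuals")
  stopifnot(length(colony) == n)
  ids <- names(uds)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- bhattacharyya(uds[[i]], uds[[j]])$si
    }
  }
  structure(m, colony = as.character(colony), class = c("segregation_matrix",
                                                        "matrix"))
}

#' Isopleth of a UD
#'
#' The smallest set of cells, filled in order of descending mass, whose
#' cumulative mass reaches `level`. Cells tied in mass at the cut are taken
#' in deterministic lattice order, keeping the set minimal.
#'
#' @param ud a `"ud"` object.
#' @param level isopleth level in (0, 1), e.g. 0.5 for the core-use area.
#' @return list with `cells` (two-column matrix of lattice indices),
#'   `area_m2`, `mass` (cumulative mass covered) and `level`.
#' @export
isopleth <- function(ud, level) {
  stopifnot(level > 0, level < 1)
  v <- as.vector(ud$mass)
  ord <- order(v, seq_along(v), decreasing = c(TRUE, FALSE),
               method = "radix")
  cum <- cumsum(v[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  sel <- ord[seq_len(k)]
  ij <- arrayInd(sel, dim(ud$mass))
  cells <- cbind(i = ij[, 1] + ud$i0 - 1L, j = ij[, 2] + ud$j0 - 1L)
  list(cells = cells, area_m2 = nrow(cells) * ud$cell^2,
       mass = cum[k], level = level)
}

#' Colony-level UD as a trip-weighted mixture of member UDs
#'
#' @param uds list of `"ud"` objects (>= 1).
#' @param weights non-negative weights, one per UD (e.g. trips per
#'   individual); default equal.
#' @return a `"ud"` object: the normalized convex combination.
#' @export
colony_ud <- function(uds, weights = NULL) {
  n <- length(uds)
  if (n < 1) stop("need >= 1 UD")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (sum(weights) == 0) stop("zero total weight")
  w <- weights / sum(weights)
  acc <- uds[[1]]
  acc_w <- w[1]
  if (n > 1) {
    for (k in 2:n) {
      g <- .union_grids(structure(list(mass = acc$mass * acc_w, i0 = acc$i0,
                                       j0 = acc$j0, cell = acc$cell),
                                  class = "ud"),
                        structure(list(mass = uds[[k]]$mass * w[k],
                                       i0 = uds[[k]]$i0, j0 = uds[[k]]$j0,
                                       cell = uds[[k]]$cell), class = "ud"))
      i0 <- min(acc$i0, uds[[k]]$i0)
      j0 <- min(acc$j0, uds[[k]]$j0)
      acc <- structure(list(mass = g[[1]] + g[[2]], i0 = i0, j0 = j0,
                            cell = acc$cell), class = "ud")
      acc_w <- 1
    }
  } else {
    acc <- structure(list(mass = acc$mass * 1, i0 = acc$i0, j0 = acc$j0,
                          cell = acc$cell), class = "ud")
  }
  ud_new(acc$mass / sum(acc$mass), acc$i0, acc$j0, acc$cell)
}

# fraction of positions falling inside an isopleth's cell set
.inclusion_rate <- function(positions, iso, cell) {
  ij <- cbind(floor(positions[, 1] / cell), floor(positions[, 2] / cell))
  key <- paste(ij[, 1], ij[, 2])
  mean(key %in% paste(iso$cells[, 1], iso$cells[, 2]))
}

#' Colony representativeness bootstrap
#'
#' How well a colony-level UD built from the sampled individuals captures
#' the colony's space use. For each subset size i = 1..N-1, `n_boot` random
#' individual subsets are drawn; the pooled subset UD's 95% isopleth is
#' scored by the fraction of the withheld individuals' fixes it contains.
#' A saturating Michaelis-Menten curve `y = a x / (b + x)` is fitted to the
#' mean inclusion rate against i, and representativeness is
#' `100 * predicted(N) / a`.
#'
#' @param uds list of `"ud"` objects (>= 3 individuals).
#' @param positions list of projected fix matrices, same order as `uds`.
#' @param n_boot bootstrap draws per subset size, default 50.
#' @param level isopleth level used for inclusion, default 0.95.
#' @param seed RNG seed.
#' @return list with `percent` (representativeness, or `NA` on fit
#'   failure), `curve` (data frame of subset size and mean inclusion),
#'   `fit_ok` flag.
#' @export
representativeness <- function(uds, positions, n_boot = 50, level = 0.95,
                               seed = 1L) {
  N <- length(uds)
  if (N < 3) stop("need >= 3 individuals")
  stopifnot(length(positions) == N)
  withr::with_seed(seed, {
    sizes <- seq_len(N - 1)
    mean_inc <- vapply(sizes, function(i) {
      incs <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(N, i)
        pooled <- colony_ud(uds[idx])
        iso <- isopleth(pooled, level)
        held <- do.call(rbind, positions[-idx])
        .inclusion_rate(held, iso, pooled$cell)
      }, 0)
      mean(incs)
    }, 0)
  })
  curve <- data.frame(size = sizes, inclusion = mean_inc)
  fit <- tryCatch(
    minpack.lm::nlsLM(inclusion ~ a * size / (b + size), data = curve,
                      start = list(a = max(mean_inc), b = 1),
                      lower = c(1e-6, 1e-6)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(percent = NA_real_, curve = curve, fit_ok = FALSE))
  }
  cf <- stats::coef(fit)
  pred_N <- cf["a"] * N / (cf["b"] + N)
  list(percent = unname(100 * pred_N / cf["a"]), curve = curve,
       fit_ok = TRUE)
}

#' Write a UD as ESRI-ASCII-grid-style text with a JSON sidecar
#'
#' @param ud a `"ud"` object.
#' @param path output path (`.asc`); metadata goes to `<path>.json`.
#' @param meta optional list of model metadata for the sidecar.
#' @export
write_ud <- function(ud, path, meta = list()) {
  nr <- ncol(ud$mass)  # ascii grid rows = y
  nc <- nrow(ud$mass)
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.3f", ud$i0 * ud$cell),
           sprintf("yllcorner %.3f", ud$j0 * ud$cell),
           sprintf("cellsize %g", ud$cell), "NODATA_value -9999")
  rows <- vapply(rev(seq_len(nr)), function(j) {
    paste(sprintf("%.10e", ud$mass[, j]), collapse = " ")
  }, "")
  writeLines(c(hdr, rows), path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a segregation matrix as square delimited text
#'
#' @param m a `"segregation_matrix"`.
#' @param path output path.
#' @export
write_segregation_matrix <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
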