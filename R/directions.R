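#' Uniform antipodally-symmetric direction lookup table
#'
#' Walkers draw step directions from a pre-allocated table of unit vectors.
#' The table is built by minimizing the antipodal electrostatic-repulsion
#' energy \deqn{E = \sum_{i<j} 1/\|u_i - u_j\| + 1/\|u_i + u_j\|} over
#' `n_independent` unit vectors by projected gradient descent with an
#' adaptive step, starting from a seeded random configuration; the final
#' table is the optimized set together with its antipodes, so every direction
#' `u` appears with `-u`. The default table holds 8,000 directions (4,000
#' independent).
#'
#' @param n_independent number of independent orientations (>= 2)
#' @param iterations maximum gradient-descent iterations
#' @param seed RNG seed for the random start
#' @param tol relative energy-change convergence tolerance
#' @return an `n x 3` matrix of unit vectors (class `direction_table`) with
#'   attributes `energy`, `iterations`, `converged`, `n_independent`, `seed`
#' @export
generate_direction_table <- function(n_independent = 4000, iterations = 1500,
                                     seed = 20130101, tol = 1e-10) {
  if (n_independent < 2) stop("need at least 2 independent directions")
  res <- cpp_optimize_directions(as.integer(n_independent),
                                 as.integer(iterations), as.numeric(seed), tol)
  if (!res$converged)
    warning("direction optimization hit the iteration cap; returning best iterate")
  tab <- rbind(res$directions, -res$directions)
  structure(tab, class = c("direction_table", "matrix", "array"),
            energy = res$energy, iterations = res$iterations,
            converged = res$converged, n_independent = n_independent,
            seed = seed)
}

#' @export
print.direction_table <- function(x, ...) {
  st <- neighbor_angle_stats(x)
  cat(sprintf("direction_table: %d directions (%d independent), nearest-neighbor angle %.2f/%.2f/%.2f deg (mean/min/max), sd %.2f\n",
              nrow(x), attr(x, "n_independent"), st$mean, st$min, st$max, st$sd))
  invisible(x)
}

#' Nearest-neighbor angle statistics of a direction table
#'
#' For each direction, the angle to its nearest other direction, summarized
#' as mean/min/max/standard deviation in degrees.
#'
#' @param table an n x 3 matrix of unit vectors
#' @return list with `mean`, `min`, `max`, `sd` (degrees) and the per-
#'   direction vector `angles`
#' @export
neighbor_angle_stats <- function(table) {
  table <- unclass(table)
  stopifnot(nrow(table) >= 2)
  ang <- cpp_nn_angles(matrix(as.numeric(table), ncol = 3))
  list(mean = mean(ang), min = min(ang), max = max(ang), sd = sd(ang),
       angles = ang)
}

# Session cache for expensive tables (regenerated on demand, cached on disk).
.table_cache <- new.env(parent = emptyenv())

#' Default direction lookup table (cached)
#'
#' Returns the table for the requested size, generating it on first use and
#' caching it in the session and (best-effort) in the user cache directory.
#'
#' @param n_independent independent orientation count
#' @param seed optimizer seed
#' @return a `direction_table`
#' @export
default_direction_table <- function(n_independent = 4000, seed = 20130101) {
  key <- sprintf("tab_%d_%d", n_independent, seed)
  if (!is.null(.table_cache[[key]])) return(.table_cache[[key]])
  cache_dir <- tryCatch(tools::R_user_dir("dmrimc", "cache"), error = function(e) NULL)
  f <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".rds")) else NULL
  tab <- NULL
  if (!is.null(f) && file.exists(f))
    tab <- tryCatch(readRDS(f), error = function(e) NULL)
  if (is.null(tab)) {
    tab <- generate_direction_table(n_independent, seed = seed)
    if (!is.null(f)) {
      tryCatch({
        dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(tab, f)
      }, error = function(e) NULL)
    }
  }
  .table_cache[[key]] <- tab
  tab
}
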