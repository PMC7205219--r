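#' Specification of an estimation-error look-up table
#'
#' Defines the Monte-Carlo grid for the estimation-error table: for every
#' combination of trajectory length and localization error, trajectories
#' with a known true diffusivity are simulated and the magnitude of the
#' percent error of the posterior-mode estimate is averaged over
#' replicates. The resulting table predicts, for an experimentalist's
#' tracking conditions, how accurate single-trajectory diffusivity
#' estimation will be.
#'
#' @param diffusivity true diffusion coefficient D, um^2/s, > 0.
#' @param lengths strictly increasing grid of trajectory lengths
#'   (frame-to-frame steps). Default log-spaced 10 .. 10^4.
#' @param loc_errors strictly increasing grid of localization error SDs,
#'   um. Default \code{c(0, 0.01, 0.05, 0.1, 0.2)}.
#' @param n_replicates simulated trajectories per grid cell (default
#'   10^4, the resolution used for published-quality tables; a few
#'   hundred suffices for exploratory maps).
#' @param dt frame interval, s.
#' @param n_dim spatial dimensionality.
#' @param hurst Hurst coefficient; 0.5 for Brownian trajectories,
#'   otherwise fractional Brownian motion analyzed with the unmodified
#'   pure-diffusion posterior.
#' @param master_seed integer seed from which every cell derives its own
#'   child seed, making the table reproducible and cell-order
#'   independent.
#' @return An object of class \code{"error_table_spec"}.
#' @export
error_table_spec <- function(diffusivity = 0.1,
                             lengths = c(10, 100, 1000, 10000),
                             loc_errors = c(0, 0.01, 0.05, 0.1, 0.2),
                             n_replicates = 10000, dt = 1, n_dim = 2,
                             hurst = 0.5, master_seed = 1) {
  check_grid(lengths, "lengths")
  if (any(loc_errors < 0) || is.unsorted(loc_errors, strictly = TRUE))
    stop("'loc_errors' must be a non-negative strictly increasing grid",
         call. = FALSE)
  if (diffusivity <= 0) stop("'diffusivity' must be positive", call. = FALSE)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1", call. = FALSE)
  structure(list(diffusivity = diffusivity, lengths = as.integer(lengths),
                 loc_errors = loc_errors,
                 n_replicates = as.integer(n_replicates), dt = dt,
                 n_dim = as.integer(n_dim), hurst = hurst,
                 master_seed = as.integer(master_seed)),
            class = "error_table_spec")
}

#' Specification of a KL-distinguishability look-up table
#'
#' Defines the Monte-Carlo grid for the distinguishability table: for
#' every combination of diffusivity ratio and trajectory length, a pair
#' of trajectories with diffusivities D1 and D2 = ratio * D1 is
#' simulated, a posterior fitted to each, and their symmetrized KL
#' divergence averaged over replicates. The table predicts how long
#' trajectories must be before a given fold-difference in diffusivity
#' becomes detectable.
#'
#' @param base_diffusivity D1, um^2/s, > 0.
#' @param ratios positive grid of D2/D1 values.
#' @param lengths strictly increasing grid of trajectory lengths (steps).
#' @param loc_error single localization error SD applied to both members
#'   of every pair, um.
#' @inheritParams error_table_spec
#' @return An object of class \code{"kl_table_spec"}.
#' @export
kl_table_spec <- function(base_diffusivity = 0.1,
                          ratios = c(1, 1.5, 2, 3, 5, 10),
                          lengths = c(10, 100, 1000, 10000),
                          loc_error = 0, n_replicates = 10000, dt = 1,
                          n_dim = 2, master_seed = 1) {
  check_grid(lengths, "lengths")
  if (any(ratios <= 0) || length(ratios) == 0)
    stop("'ratios' must be positive", call. = FALSE)
  if (base_diffusivity <= 0)
    stop("'base_diffusivity' must be positive", call. = FALSE)
  if (loc_error < 0) stop("'loc_error' must be >= 0", call. = FALSE)
  structure(list(base_diffusivity = base_diffusivity, ratios = ratios,
                 lengths = as.integer(lengths), loc_error = loc_error,
                 n_replicates = as.integer(n_replicates), dt = dt,
                 n_dim = as.integer(n_dim),
                 master_seed = as.integer(master_seed)),
            class = "kl_table_spec")
}

check_grid <- function(x, name) {
  if (length(x) == 0 || any(x < 1) || is.unsorted(x, strictly = TRUE))
    stop("'", name, "' must be a non-empty strictly increasing grid",
         call. = FALSE)
}

# Deterministic, order-independent child seeds for n_cells Monte-Carlo
# cells: drawn once from the master seed, indexed by cell position.
cell_seeds <- function(master_seed, n_cells) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n_cells)
}

#' Monte-Carlo estimation-error look-up table
#'
#' Runs the full simulate-and-infer pipeline for every grid cell of the
#' spec: trajectories are simulated (Brownian at \code{hurst = 0.5},
#' fractional Brownian otherwise), the conjugate diffusivity posterior is
#' fitted to the observed (noisy) positions with the uninformative prior,
#' and the magnitude of the percent error of the posterior mode against
#' the true diffusivity is averaged over replicates. Deterministic for a
#' given \code{master_seed}.
#'
#' @param spec an [error_table_spec()].
#' @return An object of class \code{"error_table"}: the \code{spec},
#'   \code{values} (lengths x loc_errors matrix of mean percent-error
#'   magnitudes), \code{standard_errors} (matching matrix of standard
#'   errors of the mean) and \code{n_excluded} (count of degenerate
#'   replicates, normally 0).
#' @examples
#' \donttest{
#' tab <- error_table(error_table_spec(lengths = c(10, 100),
#'                                     loc_errors = c(0, 0.1),
#'                                     n_replicates = 200))
#' tab$values
#' }
#' @export
error_table <- function(spec) {
  stopifnot(inherits(spec, "error_table_spec"))
  nl <- length(spec$lengths)
  ne <- length(spec$loc_errors)
  seeds <- cell_seeds(spec$master_seed, nl * ne)
  values <- ses <- matrix(NA_real_, nl, ne,
                          dimnames = list(spec$lengths, spec$loc_errors))
  n_excluded <- 0L
  for (i in seq_len(nl)) {
    for (j in seq_len(ne)) {
      set.seed(seeds[(i - 1) * ne + j])
      cfg <- sim_config(diffusivity = spec$diffusivity,
                        n_steps = spec$lengths[i], dt = spec$dt,
                        n_dim = spec$n_dim,
                        loc_error_sd = spec$loc_errors[j],
                        hurst = spec$hurst)
      errs <- numeric(spec$n_replicates)
      ok <- logical(spec$n_replicates)
      for (r in seq_len(spec$n_replicates)) {
        traj <- if (spec$hurst == 0.5) simulate_brownian(cfg)
                else simulate_fbm_trajectory(cfg)
        post <- tryCatch(estimate_diffusivity(traj),
                         error = function(e) NULL)
        if (is.null(post)) next
        errs[r] <- percent_error(posterior_mode(post), spec$diffusivity)
        ok[r] <- TRUE
      }
      n_excluded <- n_excluded + sum(!ok)
      e <- errs[ok]
      values[i, j] <- mean(e)
      ses[i, j] <- stats::sd(e) / sqrt(length(e))
    }
  }
  if (n_excluded > 0)
    message(n_excluded, " degenerate replicate(s) excluded")
  structure(list(spec = spec, values = values, standard_errors = ses,
                 n_excluded = n_excluded),
            class = "error_table")
}

#' Monte-Carlo KL-distinguishability look-up table
#'
#' For every (ratio, length) cell, simulates a trajectory pair with
#' diffusivities D1 and D2 = ratio * D1 (same length, same localization
#' error), fits the diffusivity posterior to each, and averages the
#' symmetrized KL divergence over replicates. Deterministic for a given
#' \code{master_seed}.
#'
#' @param spec a [kl_table_spec()].
#' @return An object of class \code{"kl_table"}: the \code{spec},
#'   \code{values} (ratios x lengths matrix of mean symmetrized KL
#'   divergences), \code{standard_errors} and \code{n_excluded}.
#' @export
kl_table <- function(spec) {
  stopifnot(inherits(spec, "kl_table_spec"))
  nr <- length(spec$ratios)
  nl <- length(spec$lengths)
  seeds <- cell_seeds(spec$master_seed, nr * nl)
  values <- ses <- matrix(NA_real_, nr, nl,
                          dimnames = list(spec$ratios, spec$lengths))
  n_excluded <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nl)) {
      set.seed(seeds[(i - 1) * nl + j])
      cfg1 <- sim_config(diffusivity = spec$base_diffusivity,
                         n_steps = spec$lengths[j], dt = spec$dt,
                         n_dim = spec$n_dim, loc_error_sd = spec$loc_error)
      cfg2 <- sim_config(diffusivity = spec$base_diffusivity * spec$ratios[i],
                         n_steps = spec$lengths[j], dt = spec$dt,
                         n_dim = spec$n_dim, loc_error_sd = spec$loc_error)
      kls <- numeric(spec$n_replicates)
      ok <- logical(spec$n_replicates)
      for (r in seq_len(spec$n_replicates)) {
        res <- tryCatch({
          p1 <- estimate_diffusivity(simulate_brownian(cfg1))
          p2 <- estimate_diffusivity(simulate_brownian(cfg2))
          symmetric_kl(p1, p2)
        }, error = function(e) NULL)
        if (is.null(res)) next
        kls[r] <- res
        ok[r] <- TRUE
      }
      n_excluded <- n_excluded + sum(!ok)
      k <- kls[ok]
      values[i, j] <- mean(k)
      ses[i, j] <- stats::sd(k) / sqrt(length(k))
    }
  }
  if (n_excluded > 0)
    message(n_excluded, " degenerate replicate(s) excluded")
  structure(list(spec = spec, values = values, standard_errors = ses,
                 n_excluded = n_excluded),
            class = "kl_table")
}

#' @export
print.error_table <- function(x, ...) {
  cat(sprintf("Estimation-error look-up table (mean |%% error| of posterior mode)\n"))
  cat(sprintf("  D = %g um^2/s, H = %g, %d replicates/cell\n",
              x$spec$diffusivity, x$spec$hurst, x$spec$n_replicates))
  cat("  rows: trajectory length (steps); columns: localization error SD (um)\n")
  print(round(x$values, 2))
  invisible(x)
}

#' @export
print.kl_table <- function(x, ...) {
  cat("KL-distinguishability look-up table (mean symmetrized KL, nats)\n")
  cat(sprintf("  D1 = %g um^2/s, loc error = %g um, %d replicates/cell\n",
              x$spec$base_diffusivity, x$spec$loc_error,
              x$spec$n_replicates))
  cat("  rows: D2/D1 ratio; columns: trajectory length (steps)\n")
  print(signif(x$values, 3))
  invisible(x)
}

#' Interpolate an estimation-error table at arbitrary conditions
#'
#' Bilinear interpolation of the table on its (length, localization
#' error) grid: exact at grid nodes, linear in between. Queries outside
#' the grid hull are refused (the tables are look-up tables, not models).
#'
#' @param table an \code{"error_table"}.
#' @param length trajectory length (steps) at which to predict.
#' @param loc_error localization error SD (um) at which to predict.
#' @return Predicted mean percent-error magnitude.
#' @export
predict_error <- function(table, length, loc_error) {
  stopifnot(inherits(table, "error_table"))
  xs <- as.numeric(table$spec$lengths)
  ys <- table$spec$loc_errors
  if (length < xs[1] || length > xs[length(xs)] ||
      loc_error < ys[1] || loc_error > ys[length(ys)])
    stop(sprintf(paste0("query (length = %g, loc_error = %g) is outside the ",
                        "table grid; nearest cell is (length = %g, ",
                        "loc_error = %g) - regenerate the table with a ",
                        "wider grid"),
                 length, loc_error,
                 xs[which.min(abs(xs - length))],
                 ys[which.min(abs(ys - loc_error))]),
         call. = FALSE)
  i <- findInterval(length, xs, rightmost.closed = TRUE)
  j <- findInterval(loc_error, ys, rightmost.closed = TRUE)
  i <- min(i, base::length(xs) - 1); i <- max(i, 1)
  j <- min(j, base::length(ys) - 1); j <- max(j, 1)
  tx <- if (xs[i + 1] > xs[i]) (length - xs[i]) / (xs[i + 1] - xs[i]) else 0
  ty <- if (ys[j + 1] > ys[j]) (loc_error - ys[j]) / (ys[j + 1] - ys[j]) else 0
  v <- table$values
  (1 - tx) * (1 - ty) * v[i, j] + tx * (1 - ty) * v[i + 1, j] +
    (1 - tx) * ty * v[i, j + 1] + tx * ty * v[i + 1, j + 1]
}

#' Serialize a look-up table to long-format CSV
#'
#' One data row per grid cell with columns \code{length},
#' \code{loc_error} (or \code{ratio}), \code{mean}, \code{se}, \code{n};
#' the spec is embedded as \code{# key: value} header comments so the
#' file round-trips losslessly through [read_table_csv()].
#'
#' @param table an \code{"error_table"} or \code{"kl_table"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(table, path) {
  UseMethod("write_table_csv")
}

#' @export
write_table_csv.error_table <- function(table, path) {
  s <- table$spec
  meta <- c(kind = "error", diffusivity = s$diffusivity, dt = s$dt,
            n_dim = s$n_dim, hurst = s$hurst,
            n_replicates = s$n_replicates, master_seed = s$master_seed)
  df <- expand.grid(length = s$lengths, loc_error = s$loc_errors,
                    KEEP.OUT.ATTRS = FALSE)
  df$mean <- as.vector(table$values)
  df$se <- as.vector(table$standard_errors)
  df$n <- s$n_replicates
  write_csv_with_meta(df, meta, path)
}

#' @export
write_table_csv.kl_table <- function(table, path) {
  s <- table$spec
  meta <- c(kind = "kl", base_diffusivity = s$base_diffusivity,
            loc_error = s$loc_error, dt = s$dt, n_dim = s$n_dim,
            n_replicates = s$n_replicates, master_seed = s$master_seed)
  df <- expand.grid(ratio = s$ratios, length = s$lengths,
                    KEEP.OUT.ATTRS = FALSE)
  df$mean <- as.vector(table$values)
  df$se <- as.vector(table$standard_errors)
  df$n <- s$n_replicates
  write_csv_with_meta(df, meta, path)
}

write_csv_with_meta <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta),
                     vapply(meta, format, "", digits = 17)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a look-up table written by [write_table_csv()]
#'
#' @param path CSV file with \code{# key: value} metadata headers.
#' @return An \code{"error_table"} or \code{"kl_table"}, reconstructed
#'   exactly (standard errors included; \code{n_excluded} is not
#'   serialized and reads back as \code{NA}).
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", meta_lines), ": ", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  num <- function(k) as.numeric(meta[[k]])
  if (meta[["kind"]] == "error") {
    spec <- error_table_spec(diffusivity = num("diffusivity"),
                             lengths = sort(unique(df$length)),
                             loc_errors = sort(unique(df$loc_error)),
                             n_replicates = num("n_replicates"),
                             dt = num("dt"), n_dim = num("n_dim"),
                             hurst = num("hurst"),
                             master_seed = num("master_seed"))
    nl <- length(spec$lengths); ne <- length(spec$loc_errors)
    structure(list(spec = spec,
                   values = matrix(df$mean, nl, ne,
                                   dimnames = list(spec$lengths,
                                                   spec$loc_errors)),
                   standard_errors = matrix(df$se, nl, ne,
                                            dimnames = list(spec$lengths,
                                                            spec$loc_errors)),
                   n_excluded = NA_integer_),
              class = "error_table")
  } else {
    spec <- kl_table_spec(base_diffusivity = num("base_diffusivity"),
                          ratios = sort(unique(df$ratio)),
                          lengths = sort(unique(df$length)),
                          loc_error = num("loc_error"),
                          n_replicates = num("n_replicates"),
                          dt = num("dt"), n_dim = num("n_dim"),
                          master_seed = num("master_seed"))
    nr <- length(spec$ratios); nl <- length(spec$lengths)
    structure(list(spec = spec,
                   values = matrix(df$mean, nr, nl,
                                   dimnames = list(spec$ratios,
                                                   spec$lengths)),
                   standard_errors = matrix(df$se, nr, nl,
                                            dimnames = list(spec$ratios,
                                                            spec$lengths)),
                   n_excluded = NA_integer_),
              class = "kl_table")
  }
}

#' Heatmap of a look-up table
#'
#' Base-graphics heatmap on log-spaced axes, in the orientation of the
#' printed tables: trajectory length on the x axis.
#'
#' @param x an \code{"error_table"} or \code{"kl_table"}.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, \code{x}.
#' @export
plot.error_table <- function(x, ...) {
  graphics::image(x = log10(as.numeric(rownames(x$values))),
                  y = seq_along(colnames(x$values)),
                  z = x$values,
                  xlab = "log10 trajectory length (steps)",
                  ylab = "localization error grid index",
                  main = "Mean |% error| of posterior-mode diffusivity", ...)
  invisible(x)
}

#' @rdname plot.error_table
#' @export
plot.kl_table <- function(x, ...) {
  graphics::image(x = seq_along(rownames(x$values)),
                  y = log10(as.numeric(colnames(x$values))),
                  z = log10(x$values),
                  xlab = "D2/D1 ratio grid index",
                  ylab = "log10 trajectory length (steps)",
                  main = "log10 mean symmetrized KL divergence", ...)
  invisible(x)
}
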