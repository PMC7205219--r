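#' Write trajectories to a tracking CSV file
#'
#' Writes one or more trajectories in the common tracking-table layout:
#' one row per frame with columns \code{track_id}, \code{frame},
#' \code{t_sec}, \code{x_um}, \code{y_um} (and \code{z_um} in 3D; 1D
#' tracks carry only \code{x_um}). Observed (noisy) positions are
#' written, as a tracker would report them. Coordinates survive a
#' write/read round trip to better than 1e-9 um.
#'
#' @param trajs a single \code{"spt_trajectory"} or a (optionally named)
#'   list of them; names become track ids.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "spt_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1,
            all(vapply(trajs, inherits, TRUE, "spt_trajectory")))
  ids <- names(trajs)
  if (is.null(ids)) ids <- as.character(seq_along(trajs))
  coord_names <- c("x_um", "y_um", "z_um")
  rows <- lapply(seq_along(trajs), function(i) {
    pos <- trajs[[i]]$positions_observed
    df <- data.frame(track_id = ids[i],
                     frame = seq_len(nrow(pos)) - 1L,
                     t_sec = trajs[[i]]$times)
    for (k in seq_len(ncol(pos))) df[[coord_names[k]]] <- pos[, k]
    df
  })
  d <- ncol(trajs[[1]]$positions_observed)
  if (!all(vapply(trajs, function(t) ncol(t$positions_observed), 0L) == d))
    stop("all trajectories in one file must share the same dimensionality",
         call. = FALSE)
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from a tracking CSV file
#'
#' Parses the CSV layout written by [write_trajectories()] (track_id,
#' frame, t_sec, then coordinate columns x_um[, y_um[, z_um]]), which
#' matches the delimited "spots"-table exports of common particle
#' trackers. Frames within each track must be uniformly spaced in time.
#'
#' @param path input CSV path with a header row.
#' @return A named list of \code{"spt_trajectory"} objects (with
#'   \code{positions_true} set equal to the observed positions, since the
#'   noise-free path of a real track is unknown).
#' @export
read_trajectories <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("could not parse '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  required <- c("track_id", "frame", "t_sec", "x_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("trajectory file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  coord_cols <- intersect(c("x_um", "y_um", "z_um"), names(df))
  bad <- which(!stats::complete.cases(df[c("frame", "t_sec", coord_cols)]))
  if (length(bad) > 0)
    stop("malformed trajectory row at line ", bad[1] + 1L, " of '", path,
         "'", call. = FALSE)
  trajs <- lapply(split(df, df$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    pos <- as.matrix(tr[coord_cols])
    dimnames(pos) <- NULL
    new_trajectory(times = tr$t_sec, positions_true = pos,
                   positions_observed = pos, config = NULL)
  })
  trajs[order(names(trajs))]
}

#' Summarize diffusivity posteriors for a set of trajectories as a table
#'
#' Runs [estimate_diffusivity()] on each trajectory and collects one row
#' per track: the number of pooled step components N, the inverse-gamma
#' parameters a and b (diffusivity scale, um^2/s), the posterior mode
#' and the central credible-interval bounds. Degenerate tracks (fewer
#' than 2 frames, or all positions identical under the improper prior)
#' are skipped with a warning.
#'
#' @param trajs named list of \code{"spt_trajectory"} objects.
#' @param prior a [prior_spec()].
#' @param level credible level for the interval columns (default 0.9).
#' @return data.frame with columns \code{track_id}, \code{n_steps},
#'   \code{a}, \code{b}, \code{mode}, \code{lower}, \code{upper}.
#' @export
posterior_table <- function(trajs, prior = prior_spec(), level = 0.9) {
  stopifnot(is.list(trajs))
  ids <- names(trajs)
  if (is.null(ids)) ids <- as.character(seq_along(trajs))
  rows <- list()
  for (i in seq_along(trajs)) {
    fit <- tryCatch({
      steps <- extract_steps(trajs[[i]])
      post <- to_diffusivity_posterior(fit_variance_posterior(steps, prior))
      list(steps = steps, post = post)
    }, error = function(e) {
      warning("track '", ids[i], "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(fit)) next
    post <- fit$post
    ci <- posterior_interval(post, level)
    rows[[length(rows) + 1]] <-
      data.frame(track_id = ids[i],
                 n_steps = fit$steps$n_components,
                 a = post$shape_a, b = post$scale_b,
                 mode = posterior_mode(post),
                 lower = unname(ci["lower"]), upper = unname(ci["upper"]),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop("no track yielded a proper posterior", call. = FALSE)
  do.call(rbind, rows)
}

#' Read a flat key: value run configuration file
#'
#' One \code{key: value} pair per line; blank lines and \code{#} comments
#' are ignored. Keys must belong to \code{allowed}; unknown keys are
#' rejected so that typos never silently fall back to defaults.
#'
#' @param path config file path.
#' @param allowed character vector of permitted keys.
#' @return Named list of values (numeric where possible).
#' @export
read_run_config <- function(path, allowed = NULL) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  parts <- regmatches(lines, regexec("^([^:]+):(.*)$", lines))
  bad <- which(vapply(parts, length, 0L) != 3)
  if (length(bad) > 0)
    stop("config line ", bad[1], " is not 'key: value': '", lines[bad[1]],
         "'", call. = FALSE)
  keys <- trimws(vapply(parts, `[`, "", 2))
  vals <- trimws(vapply(parts, `[`, "", 3))
  if (anyDuplicated(keys))
    stop("duplicate config key: ", keys[duplicated(keys)][1], call. = FALSE)
  if (!is.null(allowed)) {
    unknown <- setdiff(keys, allowed)
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  vals <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(vals, keys)
}

# Write the fully-resolved parameter set next to an output file so that
# any run can be reproduced from its sidecar alone.
write_config_sidecar <- function(params, out_path) {
  sidecar <- paste0(out_path, ".config.txt")
  writeLines(sprintf("%s: %s", names(params),
                     vapply(params, function(v) format(v, digits = 17), "")),
             sidecar)
  invisible(sidecar)
}
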