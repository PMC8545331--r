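# Result serialization: flat TSV mirrors for diffability plus one
# hierarchical JSON results file per run with groups
# {meta, trajectory, sensitivities, gradient}.

#' Write a trajectory as a column-oriented TSV table
#'
#' Columns: `time`, one per state, one per observable.
#'
#' @param traj an `ode_trajectory`.
#' @param path output file.
#' @return invisibly, the written data.frame.
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- data.frame(time = traj$times)
  for (j in seq_len(ncol(traj$x))) df[[colnames(traj$x)[j]]] <- traj$x[, j]
  for (j in seq_len(ncol(traj$y))) df[[colnames(traj$y)[j]]] <- traj$y[, j]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a hierarchical results file (grouped JSON)
#'
#' Groups: `meta` (free-form run description), `trajectory` (time, x, y,
#' solver stats), optional `sensitivities` (sx, sy) and optional `gradient`
#' (value, gradient, method).
#'
#' @param path output file.
#' @param meta named list of run metadata.
#' @param traj an `ode_trajectory`, or `NULL`.
#' @param sens a `forward_sensitivities`, or `NULL`.
#' @param gradient a `gradient_result`, or `NULL`.
#' @return invisibly, the path.
#' @export
write_results_json <- function(path, meta = list(), traj = NULL,
                               sens = NULL, gradient = NULL) {
  out <- list(meta = meta)
  if (!is.null(traj))
    out$trajectory <- list(time = traj$times,
                           x = unname(apply(traj$x, 1L, identity,
                                            simplify = FALSE)),
                           states = colnames(traj$x),
                           y = unname(apply(traj$y, 1L, identity,
                                            simplify = FALSE)),
                           observables = colnames(traj$y),
                           stats = as.list(traj$stats))
  if (!is.null(sens))
    out$sensitivities <- list(
      sx = unname(lapply(seq_len(dim(sens$sx)[1L]), function(i)
        unname(as.matrix(sens$sx[i, , , drop = TRUE])))),
      sy = unname(lapply(seq_len(dim(sens$sy)[1L]), function(i)
        unname(as.matrix(sens$sy[i, , , drop = TRUE])))))
  if (!is.null(gradient))
    out$gradient <- list(value = gradient$value,
                         gradient = as.list(gradient$gradient),
                         method = gradient$method)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
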