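#' Save / load a paired recording
#'
#' The on-disk container is a directory holding a `meta.json` sidecar (format
#' version, pair metadata, per-sweep attributes, optional simulator ground
#' truth) and one CSV per sweep with columns `time_ms`, `v_cmd_mV`,
#' `i_pre_pA`, `i_post_pA`. Sample values are written with full double
#' precision (17 significant digits) so that `load_pair(save_pair(x))`
#' reproduces every sample bit-exactly.
#'
#' @param pair a [pair_record()].
#' @param path directory to create/read. `save_pair` overwrites existing
#'   sweep files in it.
#' @return `save_pair` returns `path` invisibly; `load_pair` returns the
#'   reconstructed [pair_record()].
#' @export
save_pair <- function(pair, path) {
  stopifnot(inherits(pair, "pair_record"))
  dir.create(file.path(path, "sweeps"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format = "pairsynapse-container", version = CONTAINER_VERSION,
    pair_id = pair$pair_id, position = pair$position,
    holding_v_pre = pair$holding_v_pre, holding_v_post = pair$holding_v_post,
    ljp_pre = pair$ljp_pre, ljp_post = pair$ljp_post,
    sr_class = pair$sr_class,
    qc = if (!is.null(pair$qc)) unclass(pair$qc),
    truth = if (!is.null(pair$truth)) truth_to_list(pair$truth),
    sweeps = lapply(seq_along(pair$sweeps), function(k) {
      s <- pair$sweeps[[k]]
      list(file = sprintf("sweeps/sweep_%03d.csv", k), t0 = s$t0, dt = s$dt,
           protocol_tag = s$protocol_tag,
           epoch_table = if (!is.null(s$epoch_table)) s$epoch_table)
    })
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", pretty = TRUE)
  for (k in seq_along(pair$sweeps)) {
    s <- pair$sweeps[[k]]
    df <- data.frame(time_ms = sweep_time(s), v_cmd_mV = s$v_cmd,
                     i_pre_pA = s$i_pre, i_post_pA = s$i_post)
    con <- file(file.path(path, sprintf("sweeps/sweep_%03d.csv", k)), "w")
    writeLines(paste(names(df), collapse = ","), con)
    writeLines(do.call(paste, c(lapply(df, format_dbl), sep = ",")), con)
    close(con)
  }
  invisible(path)
}

CONTAINER_VERSION <- "1.0"

format_dbl <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

#' @rdname save_pair
#' @export
load_pair <- function(path) {
  mpath <- file.path(path, "meta.json")
  if (!file.exists(mpath))
    stop("corrupt container: missing ", mpath)
  meta <- jsonlite::read_json(mpath)   # no simplification; converted below
  if (!identical(meta$format, "pairsynapse-container"))
    stop("corrupt container: ", mpath, " is not a pairsynapse container")
  if (!identical(meta$version, CONTAINER_VERSION))
    stop("container version mismatch: file has ", meta$version,
         ", this package reads ", CONTAINER_VERSION)
  if (is.null(meta$sweeps) || !dir.exists(file.path(path, "sweeps")))
    stop("corrupt container: missing /sweeps group in ", path)
  sweeps <- unname(lapply(meta$sweeps, function(sm) {
    f <- file.path(path, sm$file)
    if (!file.exists(f)) stop("corrupt container: missing dataset ", sm$file)
    df <- utils::read.csv(f, colClasses = "numeric")
    et <- json_df(sm$epoch_table)
    sweep_record(df$v_cmd_mV, df$i_pre_pA, df$i_post_pA, dt = sm$dt,
                 t0 = sm$t0, protocol_tag = sm$protocol_tag,
                 epoch_table = et, check_rate = FALSE)
  }))
  qc <- meta$qc
  if (!is.null(qc)) {
    qc <- do.call(qc_result, lapply(qc[c("leak_pre", "leak_post", "rs_pre",
                                         "rs_post", "cm_post", "rm_post")],
                                    function(v) if (is.null(v)) NA_real_ else as.numeric(v)))
  }
  pr <- pair_record(meta$pair_id, sweeps, position = meta$position,
                    holding_v_pre = meta$holding_v_pre,
                    holding_v_post = meta$holding_v_post,
                    ljp_pre = meta$ljp_pre, ljp_post = meta$ljp_post,
                    qc = qc,
                    truth = if (!is.null(meta$truth)) truth_from_list(meta$truth))
  if (!is.null(meta$sr_class)) pr$sr_class <- meta$sr_class
  pr
}

# columns-format JSON object -> data frame (NULL for empty/missing)
json_df <- function(lst) {
  if (is.null(lst) || !length(lst)) return(NULL)
  cols <- lapply(lst, function(col)
    if (!length(col)) numeric(0) else unlist(col, use.names = FALSE))
  n <- unique(vapply(cols, length, integer(1)))
  if (length(n) != 1) return(NULL)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

truth_to_list <- function(truth) unclass(truth)

truth_from_list <- function(lst) {
  out <- lapply(lst, function(v)
    if (is.list(v)) v else v)
  scalars <- setdiff(names(out), "event_times")
  for (nm in scalars)
    if (!is.null(out[[nm]]) && is.list(out[[nm]]))
      out[[nm]] <- unlist(out[[nm]], use.names = FALSE)
  out$event_times <- json_df(lst$event_times)
  structure(out, class = "ground_truth")
}
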