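#' Read a fluorescence trace CSV
#'
#' Expects a header row with columns `time_s` and `F` (one file per cell).
#'
#' @param path CSV file path.
#' @return data.frame with `time_s` and `F`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "F") %in% names(df)))
    stop("trace CSV must have columns `time_s` and `F`")
  df[, c("time_s", "F")]
}

#' Read a stimulation protocol from YAML or JSON
#'
#' Recognised keys: `burst_duration`, `intra_burst_rate`, `pulse_width_ms`,
#' `inter_burst_period`, `total_duration` (all optional; defaults are the
#' standard 1 s @ 10 Hz / 10 s / 180 s burst protocol).
#'
#' @param path `.yaml`/`.yml` or `.json` file path.
#' @return A [stim_protocol()].
#' @export
read_protocol <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(stim_protocol)))
  do.call(stim_protocol, cfg[keep])
}

#' Read a Ct table and its condition map
#'
#' The Ct CSV has genes as rows (first column = gene id) and samples as
#' columns; the condition CSV maps `sample` to `condition`.
#'
#' @param ct_path CSV of Ct values.
#' @param conditions_path CSV with columns `sample` and `condition`.
#' @param hk_genes,reference,efficiency passed to [ct_table()].
#' @return A [ct_table()].
#' @export
read_ct_table <- function(ct_path, conditions_path, hk_genes, reference,
                          efficiency = 2) {
  ct <- utils::read.csv(ct_path, row.names = 1, check.names = FALSE)
  map <- utils::read.csv(conditions_path)
  if (!all(c("sample", "condition") %in% names(map)))
    stop("condition CSV must have columns `sample` and `condition`")
  idx <- match(colnames(ct), map$sample)
  if (anyNA(idx)) stop("every Ct sample column needs a condition")
  ct_table(as.matrix(ct), conditions = map$condition[idx],
           hk_genes = hk_genes, reference = reference,
           efficiency = efficiency)
}

#' Read a striation line-profile CSV
#'
#' @param path CSV with columns `position_um` and `intensity`.
#' @return data.frame with `position_um` and `intensity`.
#' @export
read_striation_profile <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(df)))
    stop("profile CSV must have columns `position_um` and `intensity`")
  df[, c("position_um", "intensity")]
}
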