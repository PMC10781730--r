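# Trial serialization: tidy CSV for the trajectories plus a JSON sidecar for
# subject constants and provenance.

#' Write a trial to CSV (+ JSON sidecar)
#'
#' Columns: `t`, `com_x/y/z`, `footR_x/y/z`, `footL_x/y/z`, `contactR`,
#' `contactL`.  Subject constants and provenance go to a JSON sidecar
#' (default: same path with extension `.json`).
#'
#' @param trial a [trial] object.
#' @param path CSV output path.
#' @param json_path sidecar path; `NULL` derives it from `path`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", path)
  df <- data.frame(t = trial$t,
                   com_x = trial$com[, 1], com_y = trial$com[, 2],
                   com_z = trial$com[, 3],
                   footR_x = trial$foot_R[, 1], footR_y = trial$foot_R[, 2],
                   footR_z = trial$foot_R[, 3],
                   footL_x = trial$foot_L[, 1], footL_y = trial$foot_L[, 2],
                   footL_z = trial$foot_L[, 3])
  if (!is.null(trial$contact_R)) {
    df$contactR <- as.integer(trial$contact_R)
    df$contactL <- as.integer(trial$contact_L)
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(M = trial$M, L_bio = trial$L_bio, g = trial$g,
               provenance = trial$provenance,
               noise_seed = trial$noise_seed,
               n_strides = if (is.na(trial$n_strides)) NULL else trial$n_strides)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial from CSV (+ JSON sidecar)
#'
#' @param path CSV path written by [write_trial()] (or any file with the
#'   same columns).
#' @param json_path sidecar path; `NULL` derives it from `path`.
#' @param M,L_bio,g subject constants, required if no sidecar exists.
#' @return A [trial] object.
#' @export
read_trial <- function(path, json_path = NULL, M = NULL, L_bio = NULL,
                       g = 9.81) {
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(json_path)) jsonlite::read_json(json_path) else list()
  M <- if (!is.null(meta$M)) meta$M else M
  L_bio <- if (!is.null(meta$L_bio)) meta$L_bio else L_bio
  g <- if (!is.null(meta$g)) meta$g else g
  if (is.null(M) || is.null(L_bio))
    stop("subject constants M and L_bio required (no JSON sidecar found)")
  df <- utils::read.csv(path)
  need <- c("t", "com_x", "com_y", "com_z", "footR_x", "footR_y", "footR_z",
            "footL_x", "footL_y", "footL_z")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  has_contact <- all(c("contactR", "contactL") %in% names(df))
  new_trial(t = df$t,
            com = as.matrix(df[, c("com_x", "com_y", "com_z")]),
            foot_R = as.matrix(df[, c("footR_x", "footR_y", "footR_z")]),
            foot_L = as.matrix(df[, c("footL_x", "footL_y", "footL_z")]),
            contact_R = if (has_contact) df$contactR > 0 else NULL,
            contact_L = if (has_contact) df$contactL > 0 else NULL,
            M = M, L_bio = L_bio, g = g,
            provenance = if (!is.null(meta$provenance)) meta$provenance
                         else "measured")
}
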