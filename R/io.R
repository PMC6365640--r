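#' Write a cohort to long-format registry CSV
#'
#' One row per patient-stage: patient id, stage index and day, the four
#' status flags, the semicolon-joined drug set, the arrival reward and the
#' baseline feature columns. A JSON sidecar (`<path>.json`) records the
#' state schema and, when supplied, the action codec, so a cohort round
#' trips losslessly.
#'
#' @param trajectories list of [trajectory()] objects.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @param codec optional [action_codec()] to embed in the sidecar.
#' @param schema a [state_schema()].
#' @return `path`, invisibly.
#' @export
write_registry <- function(trajectories, path, codec = NULL,
                           schema = state_schema()) {
  rows <- lapply(trajectories, function(tr) {
    b <- tr$baseline
    do.call(rbind, lapply(tr$records, function(r) {
      data.frame(
        patient_id = tr$patient_id,
        stage_index = r$stage_index,
        stage_time = r$stage_time,
        alive = as.integer(r$status$alive),
        acute_gvhd = as.integer(r$status$acute_gvhd),
        chronic_gvhd = as.integer(r$status$chronic_gvhd),
        relapse = as.integer(r$status$relapse),
        drugs = paste(r$action, collapse = ";"),
        reward_in = r$reward_in,
        age = b$age,
        sex = b$sex,
        donor_relation = b$donor_relation,
        donor_sex = b$donor_sex,
        comorbidities = paste(b$comorbidities, collapse = ";"),
        stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  sidecar <- list(
    schema = list(feature_names = schema$feature_names,
                  include_stage = schema$include_stage),
    codec = if (!is.null(codec)) lapply(codec$combos, as.list))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a cohort from long-format registry CSV
#'
#' @param path CSV file written by [write_registry()] (header row required).
#' @return a list with `trajectories`, `schema` and `codec` (the latter
#'   `NULL` when the sidecar carries none).
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("patient_id", "stage_index", "alive", "acute_gvhd",
            "chronic_gvhd", "relapse", "drugs", "reward_in", "age", "sex",
            "donor_relation", "donor_sex", "comorbidities")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("registry CSV missing columns: ",
                         paste(miss, collapse = ", "))
  side_path <- paste0(path, ".json")
  schema <- state_schema()
  codec <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path)
    if (!is.null(side$schema$include_stage))
      schema <- state_schema(include_stage = isTRUE(side$schema$include_stage))
    if (!is.null(side$codec))
      codec <- action_codec(lapply(side$codec, function(x) unlist(x)))
  }
  trajs <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$stage_index), , drop = FALSE]
    b <- d[1, ]
    com <- if (nzchar(b$comorbidities))
      as.integer(strsplit(b$comorbidities, ";")[[1]]) else integer(0)
    baseline <- patient_baseline(age = b$age, sex = b$sex,
                                 comorbidities = com,
                                 donor_relation = b$donor_relation,
                                 donor_sex = b$donor_sex)
    records <- lapply(seq_len(nrow(d)), function(i) {
      row <- d[i, ]
      stage_record(
        stage_index = row$stage_index,
        status = status_flags(alive = row$alive == 1,
                              acute_gvhd = row$acute_gvhd == 1,
                              chronic_gvhd = row$chronic_gvhd == 1,
                              relapse = row$relapse == 1),
        action = if (nzchar(row$drugs)) strsplit(row$drugs, ";")[[1]],
        reward_in = row$reward_in)
    })
    trajectory(b$patient_id, baseline, records)
  })
  names(trajs) <- NULL
  # restore original cohort order (split() sorts by id)
  first_seen <- unique(df$patient_id)
  ids <- vapply(trajs, function(t) as.character(t$patient_id), character(1))
  trajs <- trajs[match(as.character(first_seen), ids)]
  list(trajectories = trajs, schema = schema, codec = codec)
}
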