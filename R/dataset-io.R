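#' TDM dataset container (NONMEM-style event records)
#'
#' A data frame of dose and observation records in the community CSV
#' dialect: `ID` (subject), `TIME` (hours since first dose), `EVID`
#' (1 = dose, 0 = observation), `AMT` (dose amount, mg, dose rows only),
#' `DV` (observed concentration, mg/L, observation rows only), `BLQ`
#' (1 if the observation was below the limit of quantification), plus
#' any number of covariate columns repeated on every row of a subject.
#'
#' Validity rules: mandatory columns present; `EVID` in \{0, 1\};
#' exactly one of `AMT`/`DV` populated per row; times finite and
#' non-negative and non-decreasing within subject; every observation
#' preceded by at least one dose of the same subject; observed
#' concentrations non-negative.
#'
#' @param df A data frame in the dialect above.
#' @return `df` with class `tdm_dataset` prepended, rows ordered by
#'   subject and time.
#' @export
tdm_dataset <- function(df) {
  df <- as.data.frame(df)
  req <- c("ID", "TIME", "EVID", "AMT", "DV")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$BLQ)) df$BLQ <- 0L
  if (!all(df$EVID %in% c(0L, 1L))) stop("EVID must be 0 (observation) or 1 (dose)")
  if (any(!is.finite(df$TIME)) || any(df$TIME < 0)) {
    stop("TIME must be finite and >= 0")
  }
  is_dose <- df$EVID == 1L
  bad <- which(is_dose & (is.na(df$AMT) | !is.na(df$DV)))
  if (length(bad)) {
    stop("dose rows must have AMT set and DV empty (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  bad <- which(!is_dose & (is.na(df$DV) | !is.na(df$AMT)))
  if (length(bad)) {
    stop("observation rows must have DV set and AMT empty (rows ",
         paste(utils::head(bad, 5), collapse = ", "), ")")
  }
  if (any(df$DV[!is_dose] < 0)) stop("observed concentrations must be >= 0")
  if (any(df$AMT[is_dose] < 0)) stop("dose amounts must be >= 0")
  # preserve within-subject row order but group subjects contiguously
  df <- df[order(match(df$ID, unique(df$ID))), , drop = FALSE]
  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, ]
    if (is.unsorted(sub$TIME)) {
      stop(sprintf("times are not non-decreasing within subject %s", id))
    }
    obs_t <- sub$TIME[sub$EVID == 0L]
    if (length(obs_t)) {
      dose_t <- sub$TIME[sub$EVID == 1L]
      if (!length(dose_t) || min(obs_t) < min(dose_t)) {
        stop(sprintf("subject %s has an observation before any dose", id))
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("tdm_dataset", "data.frame")
  df
}

#' @export
print.tdm_dataset <- function(x, ...) {
  n_obs <- sum(x$EVID == 0L)
  n_blq <- sum(x$EVID == 0L & x$BLQ == 1L)
  cat(sprintf("TDM dataset: %d subjects, %d dose records, %d observations (%d BLQ)\n",
              length(unique(x$ID)), sum(x$EVID == 1L), n_obs, n_blq))
  print(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("... %d more rows\n", nrow(x) - 8))
  invisible(x)
}

#' Read / write a TDM dataset CSV
#'
#' `read_tdm` parses and validates a CSV in the [tdm_dataset()] dialect;
#' `write_tdm` writes one. A write/read round trip is the identity (up to
#' numeric formatting at full precision).
#'
#' @param path File path.
#' @return `read_tdm`: a validated [tdm_dataset()]. `write_tdm`: `path`,
#'   invisibly.
#' @export
read_tdm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tdm_dataset(df)
}

#' @rdname read_tdm
#' @param dataset A [tdm_dataset()].
#' @export
write_tdm <- function(dataset, path) {
  stopifnot(inherits(dataset, "tdm_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

## Internal: split a dataset into the per-subject pieces estimation needs,
## excluding BLQ observations (with a warning) and precomputing the
## (observation, prior-dose) pair expansion used by the superposition
## predictor.
.prepare_dataset <- function(dataset, drop_blq = TRUE, keep_empty = FALSE) {
  stopifnot(inherits(dataset, "tdm_dataset"))
  obs <- dataset[dataset$EVID == 0L, , drop = FALSE]
  if (drop_blq && any(obs$BLQ == 1L)) {
    warning(sum(obs$BLQ == 1L), " BLQ observation(s) excluded from estimation")
    obs <- obs[obs$BLQ == 0L, , drop = FALSE]
  }
  ids <- unique(dataset$ID)
  keep <- if (keep_empty) ids else ids[ids %in% obs$ID]
  dropped <- setdiff(ids, keep)
  if (length(dropped)) {
    warning("subject(s) without usable observations dropped: ",
            paste(dropped, collapse = ", "))
  }
  obs <- obs[order(match(obs$ID, keep), obs$TIME), , drop = FALSE]
  subj <- match(obs$ID, keep)
  # pair expansion: one row per (observation, dose at or before it)
  pair_obs <- integer(0); pair_tdiff <- numeric(0); pair_amt <- numeric(0)
  for (k in seq_along(keep)) {
    d <- dataset[dataset$ID == keep[k] & dataset$EVID == 1L, , drop = FALSE]
    o_idx <- which(subj == k)
    for (j in o_idx) {
      on <- which(d$TIME <= obs$TIME[j])
      pair_obs <- c(pair_obs, rep(j, length(on)))
      pair_tdiff <- c(pair_tdiff, obs$TIME[j] - d$TIME[on])
      pair_amt <- c(pair_amt, d$AMT[on])
    }
  }
  # one covariate row per retained subject
  first_row <- dataset[match(keep, dataset$ID), , drop = FALSE]
  cov_cols <- setdiff(names(dataset), c("ID", "TIME", "EVID", "AMT", "DV", "BLQ"))
  covariates <- cbind(data.frame(id = keep), first_row[, cov_cols, drop = FALSE])
  rownames(covariates) <- NULL
  list(ids = keep, n = length(keep), y = obs$DV, time = obs$TIME, subj = subj,
       n_obs = nrow(obs), pair_obs = pair_obs, pair_subj = subj[pair_obs],
       pair_tdiff = pair_tdiff, pair_amt = pair_amt, covariates = covariates)
}

## Superposition predictions for all retained observations given
## per-subject parameters (vectors over subjects).
.pred_conc <- function(prep, ka, v, cl) {
  ps <- prep$pair_subj
  c_pair <- .bateman(prep$pair_tdiff, prep$pair_amt, ka[ps], v[ps], cl[ps])
  as.numeric(rowsum(c_pair, group = prep$pair_obs, reorder = TRUE))
}
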