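#' Read a clinical records table
#'
#' TSV with columns \code{sample_id}, \code{vital_status} (\code{alive} /
#' \code{dead}), \code{gender} (\code{male} / \code{female}),
#' \code{days_to_death}, \code{days_to_last_follow_up},
#' \code{age_at_diagnosis}. Missing values may be encoded as empty, NA, or
#' the literal string \code{"nan"} (any case).
#'
#' @param path TSV file.
#' @return A data.frame with numeric time/age columns (NA where missing).
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path,
    stringsAsFactors = FALSE,
    colClasses = "character", na.strings = c("NA", "nan", "NaN", "")
  )
  required <- c(
    "sample_id", "vital_status", "gender", "days_to_death",
    "days_to_last_follow_up", "age_at_diagnosis"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("days_to_death", "days_to_last_follow_up", "age_at_diagnosis")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}

#' Derive the survival analysis table from clinical records
#'
#' Event = 1 iff vital status is dead; time is days to death for the
#' deceased, days to last follow-up otherwise. Rows with a missing required
#' value (status, gender, the applicable time field, age), a gender outside
#' \{male, female\}, or a non-positive time are dropped, with tallied
#' reasons in \code{attr(x, "tallies")}.
#'
#' @param clinical Output of [read_clinical()].
#' @return data.frame \code{sample_id}, \code{time}, \code{event} (0/1),
#'   \code{age}, \code{sex} (1 = male, 0 = female).
#' @export
derive_survival <- function(clinical) {
  df <- clinical
  tallies <- c(missing = 0L, bad_gender = 0L, nonpositive_time = 0L)
  dead <- df$vital_status == "dead"
  time <- ifelse(dead, df$days_to_death, df$days_to_last_follow_up)
  miss <- is.na(df$vital_status) | !df$vital_status %in% c("alive", "dead") |
    is.na(df$gender) | is.na(df$age_at_diagnosis) | is.na(time)
  tallies["missing"] <- sum(miss)
  keep <- !miss
  bad_gender <- keep & !df$gender %in% c("male", "female")
  tallies["bad_gender"] <- sum(bad_gender)
  keep <- keep & !bad_gender
  nonpos <- keep & time <= 0
  tallies["nonpositive_time"] <- sum(nonpos)
  keep <- keep & !nonpos
  out <- data.frame(
    sample_id = df$sample_id[keep],
    time = time[keep],
    event = as.integer(dead[keep]),
    age = df$age_at_diagnosis[keep],
    sex = as.integer(df$gender[keep] == "male"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "tallies") <- tallies
  out
}

#' Fit a Cox proportional-hazards model for one unit
#'
#' Covariates: carrier indicator (sample perturbs the unit), age at
#' diagnosis, and sex. Ties are handled by the Efron approximation. The
#' hazard ratio is the exponentiated carrier coefficient with a 95% Wald
#' confidence interval.
#'
#' Units with fewer than 2 carriers, fewer than 2 non-carriers, or no events
#' are skipped (NULL with a \code{reason} attribute), as are fits that fail
#' to converge.
#'
#' @param surv_tab Output of [derive_survival()].
#' @param carrier_ids Sample ids carrying a perturbation of the unit.
#' @return One-row data.frame \code{hazard_ratio}, \code{ci_low},
#'   \code{ci_high}, \code{p_value}, \code{n_carriers}, \code{n_total};
#'   when skipped, an object of class \code{cox_skip} carrying a
#'   \code{reason} attribute.
#' @export
fit_cox_for_unit <- function(surv_tab, carrier_ids) {
  d <- surv_tab
  d$carrier <- as.integer(d$sample_id %in% carrier_ids)
  skip <- function(reason) {
    structure(list(), class = "cox_skip", reason = reason)
  }
  if (sum(d$carrier) < 2 || sum(1 - d$carrier) < 2) {
    return(skip("no contrast"))
  }
  if (sum(d$event) < 1) {
    return(skip("no events"))
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ carrier + age + sex,
      data = d, ties = "efron"
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || is.na(stats::coef(fit)["carrier"])) {
    return(skip("no convergence"))
  }
  beta <- stats::coef(fit)["carrier"]
  se <- sqrt(diag(stats::vcov(fit)))["carrier"]
  if (!is.finite(beta) || !is.finite(se)) {
    return(skip("no convergence"))
  }
  z <- beta / se
  data.frame(
    hazard_ratio = exp(beta),
    ci_low = exp(beta - 1.959964 * se),
    ci_high = exp(beta + 1.959964 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_carriers = sum(d$carrier),
    n_total = nrow(d),
    row.names = NULL
  )
}

#' Screen perturbed units for association with overall survival
#'
#' Fits [fit_cox_for_unit()] for each eligible unit of a perturbation table,
#' taking carriers directly from the unit's incidence row (no re-derivation).
#' Eligible units are, by default, those flagged significant by the
#' enrichment test; \code{mode = "all"} screens every tested (c >= 1) unit.
#' q-values are BH-adjusted across all fitted units of the level; results are
#' sorted by q-value.
#'
#' @param table A \code{perturbation_table}.
#' @param surv_tab Output of [derive_survival()].
#' @param enrichment Enrichment results for the same level (required for
#'   \code{mode = "significant"}).
#' @param mode \code{"significant"} or \code{"all"}.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @param cancer_type Optional label.
#' @return data.frame \code{unit_id}, \code{unit_level}, \code{cancer_type},
#'   \code{hazard_ratio}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{q_value}, \code{significant}, \code{n_carriers}, \code{n_total};
#'   skipped units are listed in \code{attr(x, "skipped")}.
#' @export
run_survival_screen <- function(table, surv_tab, enrichment = NULL,
                                mode = c("significant", "all"),
                                alpha = 0.05, cancer_type = "") {
  mode <- match.arg(mode)
  cc <- unit_counts(table)
  units <- names(cc)[cc >= 1]
  if (mode == "significant") {
    if (is.null(enrichment)) {
      stop("enrichment results required for mode = 'significant'")
    }
    units <- intersect(units, enrichment$unit_id[enrichment$significant])
  }
  skipped <- data.frame(
    unit_id = character(), reason = character(),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (u in units) {
    carriers <- colnames(table$incidence)[table$incidence[u, ] == 1L]
    r <- fit_cox_for_unit(surv_tab, carriers)
    if (inherits(r, "cox_skip")) {
      skipped <- rbind(skipped, data.frame(
        unit_id = u,
        reason = attr(r, "reason") %||% "skipped",
        stringsAsFactors = FALSE
      ))
      next
    }
    r <- cbind(
      data.frame(
        unit_id = u, unit_level = table$level,
        cancer_type = cancer_type, stringsAsFactors = FALSE
      ), r
    )
    rows[[length(rows) + 1]] <- r
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      unit_id = character(), unit_level = character(),
      cancer_type = character(), hazard_ratio = numeric(),
      ci_low = numeric(), ci_high = numeric(), p_value = numeric(),
      n_carriers = integer(), n_total = integer(),
      stringsAsFactors = FALSE
    )
  }
  out$q_value <- if (nrow(out)) bh_adjust(out$p_value) else numeric()
  out$significant <- if (nrow(out)) out$q_value < alpha else logical()
  out <- out[order(out$q_value, out$p_value, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
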