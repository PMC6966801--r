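# Survey-audit pipeline: read a per-trial registry, audit each trial's
# conditional power under the current-trend and design hypotheses, and
# summarise the CP distribution the way futility surveys report it.

registry_numeric_cols <- c(
  "alpha", "planned_power", "design_effect", "total_information",
  "info_fraction", "estimate", "se", "z_value", "p_value", "reported_cp"
)

#' Read a trial registry from delimited text
#'
#' Parses the documented registry schema (see
#' `system.file("extdata", "registry_schema.csv", package = "cpaudit")`)
#' from CSV. Missing cells become `NA`; columns outside the schema are
#' preserved untouched. Domain violations (e.g. an alpha outside (0, 0.5])
#' are collected into a per-row issue table available via
#' [registry_issues()] — they are not fatal, but such fields are ignored at
#' conditional-power time. A missing or duplicated `trial_id` is a hard
#' error naming the offending rows.
#'
#' @param path Path to a CSV file with a header row.
#' @param delim Field delimiter (default comma).
#' @return A tibble of trial records with an `issues` attribute.
#' @export
read_trial_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(sprintf("registry file not found: %s", path), class = "cpaudit_io_error")
  }
  d <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                         show_col_types = FALSE,
                         col_types = readr::cols(
                           trial_id = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  if (!"trial_id" %in% names(d)) {
    abort("registry has no `trial_id` column", class = "cpaudit_io_error")
  }
  if (anyNA(d$trial_id)) {
    abort(sprintf("missing trial_id in row(s): %s",
                  paste(which(is.na(d$trial_id)), collapse = ", ")),
          class = "cpaudit_io_error")
  }
  if (anyDuplicated(d$trial_id)) {
    dup <- unique(d$trial_id[duplicated(d$trial_id)])
    abort(sprintf("duplicate trial_id(s): %s", paste(dup, collapse = ", ")),
          class = "cpaudit_io_error")
  }
  for (col in intersect(registry_numeric_cols, names(d))) {
    if (!is.numeric(d[[col]])) d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  attr(d, "issues") <- collect_registry_issues(d)
  d
}

#' @rdname read_trial_table
#' @export
read_registry <- read_trial_table

domain_rules <- list(
  alpha = function(x) x > 0 & x <= 0.5,
  planned_power = function(x) x > 0 & x < 1,
  design_effect = function(x) x != 0,
  se = function(x) x > 0,
  info_fraction = function(x) x > 0 & x <= 100,
  p_value = function(x) x > 0 & x < 1,
  reported_cp = function(x) x >= 0 & x <= 1
)

collect_registry_issues <- function(d) {
  out <- list()
  for (col in intersect(names(domain_rules), names(d))) {
    x <- d[[col]]
    bad <- !is.na(x) & !domain_rules[[col]](x)
    if (any(bad)) {
      out[[col]] <- tibble(trial_id = d$trial_id[bad], column = col,
                           value = x[bad],
                           problem = paste(col, "out of domain"))
    }
  }
  if (length(out)) bind_rows(out) else {
    tibble(trial_id = character(), column = character(),
           value = numeric(), problem = character())
  }
}

#' Per-row domain issues of a registry
#'
#' @param registry A registry read by [read_registry()] (or any registry
#'   tibble; issues are recomputed if the attribute is absent).
#' @return A tibble with columns `trial_id`, `column`, `value`, `problem`.
#' @export
registry_issues <- function(registry) {
  attr(registry, "issues") %||% collect_registry_issues(registry)
}

field <- function(rec, nm) {
  v <- rec[[nm]]
  if (is.null(v) || length(v) != 1L || is.na(v)) NULL else v
}

valid_field <- function(rec, nm, reasons) {
  v <- field(rec, nm)
  if (is.null(v)) return(list(value = NULL, reasons = reasons))
  rule <- domain_rules[[nm]]
  if (!is.null(rule) && !rule(v)) {
    return(list(value = NULL,
                reasons = c(reasons, paste(nm, "out of domain"))))
  }
  list(value = v, reasons = reasons)
}

#' Audit one trial record
#'
#' Resolves, in order of preference, the interim test statistic (`z_value`,
#' then `estimate`/`se`, then an exact `p_value`, then per-arm summaries via
#' the `interim_from_*()` converters), the information fraction
#' (`info_fraction`, then `interim_n / planned_total_n`, then the
#' information ratio `se^-2 / I_K`), and the total information (explicit
#' `total_information`, then derived from alpha, power and the design
#' effect). Conditional power is then computed under the current-trend and
#' design hypotheses, each independently allowed to fail.
#'
#' The verdict is `"computed"` when at least one CP succeeds;
#' `"reported_only"` when none succeeds but the record carries a
#' `reported_cp` (retained verbatim, never back-solved); `"insufficient"`
#' otherwise, with a machine-readable `failure_reason`. An interim at or
#' beyond full information is a failure reason, never clamped. An
#' information fraction between 1 and 100 is interpreted as a percentage,
#' logged under `assumptions`. A missing or unclear sidedness falls back to
#' `default_sidedness`, also logged.
#'
#' @param record One registry row (one-row data frame or named list).
#' @param threshold Futility threshold (default 0.15).
#' @param default_sidedness Sidedness assumed when the record's is missing
#'   or `"unclear"`.
#' @return A one-row tibble: `trial_id`, `status`, `cp_current_trend`,
#'   `cp_design`, `reported_cp`, `futile_at_threshold`, `failure_reason`,
#'   `assumptions`.
#' @export
audit_trial <- function(record, threshold = 0.15, default_sidedness = "two") {
  rec <- as.list(record)
  trial_id <- field(rec, "trial_id") %||% NA_character_
  reasons <- character()
  assumptions <- character()

  sidedness <- field(rec, "sidedness")
  if (is.null(sidedness) || !sidedness %in% c("one", "two")) {
    sidedness <- default_sidedness
    assumptions <- c(assumptions, paste0("sidedness assumed ", sidedness))
  }
  v <- valid_field(rec, "alpha", reasons); alpha <- v$value; reasons <- v$reasons
  v <- valid_field(rec, "planned_power", reasons); power <- v$value; reasons <- v$reasons
  v <- valid_field(rec, "design_effect", reasons); effect <- v$value; reasons <- v$reasons
  v <- valid_field(rec, "se", reasons); se <- v$value; reasons <- v$reasons
  estimate <- field(rec, "estimate")
  z <- field(rec, "z_value")
  i_total_explicit <- field(rec, "total_information")

  design <- NULL
  if (!is.null(alpha) && !is.null(power)) {
    design <- tryCatch(
      design_spec(alpha = alpha, sidedness = sidedness, power = power,
                  effect = effect, total_information = i_total_explicit),
      cpaudit_error = function(e) { reasons <<- c(reasons, conditionMessage(e)); NULL }
    )
  } else {
    reasons <- c(reasons, paste0(
      "design parameters missing: ",
      paste(c("alpha", "planned_power")[c(is.null(alpha), is.null(power))],
            collapse = ", ")))
  }

  # interim test statistic, best available route
  if (is.null(z) && !is.null(estimate) && !is.null(se)) z <- estimate / se
  if (is.null(z)) {
    v <- valid_field(rec, "p_value", character()); p <- v$value
    if (!is.null(p)) {
      if (isTRUE(field(rec, "p_is_bound"))) {
        reasons <- c(reasons, "p-value reported only as a bound")
      } else {
        dir <- if (!is.null(estimate) && estimate < 0) "harm" else "benefit"
        if (is.null(estimate)) {
          assumptions <- c(assumptions, "effect direction assumed benefit")
        }
        z <- z_from_pvalue(p, sidedness, dir)
      }
    } else if (isTRUE(field(rec, "p_is_bound"))) {
      reasons <- c(reasons, "p-value reported only as a bound")
    }
  }
  if (is.null(z)) {
    arm <- tryCatch(interim_from_arms(rec), cpaudit_error = function(e) NULL)
    if (!is.null(arm)) {
      estimate <- arm$estimate; se <- arm$se; z <- arm$z
      assumptions <- c(assumptions, paste0("interim rebuilt from arm summaries (",
                                           arm$method, ")"))
    }
  }
  if (is.null(z)) reasons <- c(reasons, "no interim test statistic (z, estimate/se, exact p, or arm summaries)")
  if (is.null(estimate) && !is.null(z) && !is.null(se)) estimate <- z * se

  # information fraction
  t_k <- NULL
  tf <- field(rec, "info_fraction")
  if (!is.null(tf) && tf > 1 && tf <= 100) {
    assumptions <- c(assumptions, "info_fraction interpreted as a percentage")
    tf <- tf / 100
  }
  if (!is.null(tf)) {
    if (tf >= 1) {
      reasons <- c(reasons, "interim at or beyond full information; CP undefined, report current significance instead")
    } else if (tf <= 0) {
      reasons <- c(reasons, "info_fraction out of domain")
    } else t_k <- tf
  } else {
    i_n <- field(rec, "interim_n"); p_n <- field(rec, "planned_total_n")
    if (!is.null(i_n) && !is.null(p_n) && p_n > 0) {
      r <- i_n / p_n
      assumptions <- c(assumptions, "information fraction taken as interim_n / planned_total_n")
      if (r >= 1) {
        reasons <- c(reasons, "interim at or beyond full information; CP undefined, report current significance instead")
      } else if (r <= 0) {
        reasons <- c(reasons, "interim_n out of domain")
      } else t_k <- r
    } else if (!is.null(se) && !is.null(design)) {
      t_k <- tryCatch(
        information_fraction(information_from_se(se), total_information(design)),
        cpaudit_beyond_full_error = function(e) {
          reasons <<- c(reasons, conditionMessage(e)); NULL
        },
        cpaudit_error = function(e) {
          reasons <<- c(reasons, conditionMessage(e)); NULL
        }
      )
      if (!is.null(t_k)) {
        assumptions <- c(assumptions, "information fraction derived from se^-2 / I_K")
      }
    } else {
      reasons <- c(reasons, "no information fraction (info_fraction, interim_n/planned_total_n, or se with I_K)")
    }
  }

  try_cp <- function(hyp) {
    if (is.null(z) || is.null(t_k) || is.null(design)) return(NA_real_)
    tryCatch({
      interim <- interim_state(z = z, estimate = estimate, se = se,
                               info_fraction = t_k)
      conditional_power(interim, design, hyp, threshold)$cp
    }, cpaudit_error = function(e) {
      reasons <<- c(reasons, conditionMessage(e))
      NA_real_
    })
  }
  cp_ct <- try_cp("current_trend")
  cp_de <- try_cp("design")

  reported_cp <- field(rec, "reported_cp")
  status <- if (!is.na(cp_ct) || !is.na(cp_de)) {
    "computed"
  } else if (!is.null(reported_cp)) {
    "reported_only"
  } else "insufficient"

  cp_for_flag <- if (!is.na(cp_ct)) cp_ct else cp_de
  tibble(
    trial_id = trial_id,
    status = status,
    cp_current_trend = cp_ct,
    cp_design = cp_de,
    reported_cp = reported_cp %||% NA_real_,
    futile_at_threshold = if (!is.na(cp_for_flag)) {
      classify_futility(cp_for_flag, threshold)
    } else NA,
    failure_reason = if (status == "insufficient") {
      paste(unique(reasons), collapse = "; ")
    } else NA_character_,
    assumptions = if (length(assumptions)) {
      paste(unique(assumptions), collapse = "; ")
    } else NA_character_
  )
}

# per-arm summary columns, if the registry carries them
interim_from_arms <- function(rec) {
  has <- function(...) all(vapply(c(...), function(nm) !is.null(field(rec, nm)), logical(1)))
  if (has("events_treat", "n_treat", "events_ctrl", "n_ctrl")) {
    measure <- field(rec, "measure") %||% "risk_difference"
    if (!measure %in% c("risk_difference", "log_odds_ratio")) {
      measure <- "risk_difference"
    }
    return(interim_from_binary(field(rec, "events_treat"), field(rec, "n_treat"),
                               field(rec, "events_ctrl"), field(rec, "n_ctrl"),
                               measure = measure))
  }
  if (has("mean_treat", "sd_treat", "n_treat", "mean_ctrl", "sd_ctrl", "n_ctrl")) {
    return(interim_from_continuous(
      field(rec, "mean_treat"), field(rec, "sd_treat"), field(rec, "n_treat"),
      field(rec, "mean_ctrl"), field(rec, "sd_ctrl"), field(rec, "n_ctrl")
    ))
  }
  abort_insufficient("no per-arm summary columns", missing = "arms")
}

#' Audit every trial in a registry
#'
#' Applies [audit_trial()] row by row. `trial_id` must be unique.
#'
#' @param registry A registry tibble (from [read_registry()] or
#'   [generate_registry()]).
#' @inheritParams audit_trial
#' @return A tibble with one audit row per trial.
#' @examples
#' audit_registry(generate_registry(n_trials = 8, seed = 5))
#' @export
audit_registry <- function(registry, threshold = 0.15,
                           default_sidedness = "two") {
  stopifnot(is.data.frame(registry))
  if (!"trial_id" %in% names(registry)) {
    abort("registry has no `trial_id` column", class = "cpaudit_io_error")
  }
  if (anyDuplicated(registry$trial_id)) {
    abort(sprintf("duplicate trial_id(s): %s",
                  paste(unique(registry$trial_id[duplicated(registry$trial_id)]),
                        collapse = ", ")),
          class = "cpaudit_io_error")
  }
  purrr::map(seq_len(nrow(registry)),
             function(i) audit_trial(registry[i, ], threshold,
                                     default_sidedness)) |>
    bind_rows()
}

cp_bin_labels <- c("<15%", "15-30%", "30-50%", ">=50%")

#' Bin conditional-power values
#'
#' The conventional survey bins: \[0, 0.15), \[0.15, 0.30), \[0.30, 0.50),
#' \[0.50, 1\]. Left-closed/right-open except the last bin, which is closed
#' at 1, so "less than 15%" is literal.
#'
#' @param values Probabilities in \[0, 1\] (no `NA`s).
#' @return A tibble with columns `bin` (ordered factor) and `n`; counts sum
#'   to `length(values)`.
#' @examples
#' bin_cp(c(0.05, 0.20, 0.40, 0.60))
#' @export
bin_cp <- function(values) {
  if (length(values) && (anyNA(values) || any(values < 0 | values > 1))) {
    abort_domain("conditional-power values must all be in [0, 1]")
  }
  idx <- findInterval(values, c(0.15, 0.30, 0.50)) + 1L
  tibble(
    bin = factor(cp_bin_labels, levels = cp_bin_labels, ordered = TRUE),
    n = as.integer(tabulate(idx, nbins = 4L))
  )
}

#' Summarise a survey audit
#'
#' Status counts, binned conditional-power distributions per hypothesis, and
#' (when the registry is supplied) sponsor-stratified bins plus frequency
#' tables of every categorical metadata column present. Reported-only CP
#' values are binned under the current-trend hypothesis, the convention used
#' when surveyed authors do not state their assumption. Conservation is
#' asserted on every run: status counts sum to the number of trials and bin
#' counts per hypothesis sum to the number of CP values binned there.
#'
#' @param audits Audit tibble from [audit_registry()].
#' @param registry Optional registry the audits came from (enables sponsor
#'   strata and metadata tallies); its `trial_id`s must match the audits'.
#' @return An object of class `survey_summary`; see [tidy()] and [glance()]
#'   methods, and [autoplot()] for the binned distribution.
#' @examples
#' reg <- generate_registry(n_trials = 20, seed = 2)
#' summarize_survey(audit_registry(reg), reg)
#' @export
summarize_survey <- function(audits, registry = NULL) {
  stopifnot(is.data.frame(audits))
  if (!is.null(registry)) {
    only_a <- setdiff(audits$trial_id, registry$trial_id)
    only_r <- setdiff(registry$trial_id, audits$trial_id)
    if (length(only_a) || length(only_r)) {
      abort(sprintf(
        "audit/registry key mismatch; only in audits: %s; only in registry: %s",
        paste(only_a, collapse = ", ") %||% "-",
        paste(only_r, collapse = ", ") %||% "-"
      ), class = "cpaudit_io_error")
    }
  }
  n_trials <- nrow(audits)
  status_levels <- c("computed", "reported_only", "insufficient")
  status_counts <- tibble(status = status_levels) |>
    left_join(count(audits, .data$status), by = "status") |>
    mutate(n = coalesce(.data$n, 0L))

  ct_tbl <- bind_rows(
    audits |> filter(.data$status == "computed", !is.na(.data$cp_current_trend)) |>
      transmute(trial_id = .data$trial_id, cp = .data$cp_current_trend),
    audits |> filter(.data$status == "reported_only", !is.na(.data$reported_cp)) |>
      transmute(trial_id = .data$trial_id, cp = .data$reported_cp)
  )
  de_tbl <- audits |>
    filter(.data$status == "computed", !is.na(.data$cp_design)) |>
    transmute(trial_id = .data$trial_id, cp = .data$cp_design)

  bins <- bind_rows(
    bin_cp(ct_tbl$cp) |> mutate(hypothesis = "current_trend", .before = 1),
    bin_cp(de_tbl$cp) |> mutate(hypothesis = "design", .before = 1)
  )
  stopifnot(sum(status_counts$n) == n_trials,
            sum(bins$n[bins$hypothesis == "current_trend"]) == nrow(ct_tbl),
            sum(bins$n[bins$hypothesis == "design"]) == nrow(de_tbl))

  bins_by_sponsor <- NULL
  tallies <- list()
  if (!is.null(registry)) {
    if ("sponsor" %in% names(registry)) {
      sp <- registry |> select("trial_id", "sponsor")
      bins_by_sponsor <- ct_tbl |>
        left_join(sp, by = "trial_id") |>
        mutate(sponsor = coalesce(.data$sponsor, "unknown")) |>
        group_by(.data$sponsor) |>
        reframe(bin_cp(.data$cp))
    }
    meta_cols <- intersect(
      c("sponsor", "outcome_kind", "measure", "sidedness", "dsmb",
        "decision_maker", "data_collection_continued"),
      names(registry)
    )
    tallies <- purrr::map(setNames(meta_cols, meta_cols),
                          function(col) count(registry, .data[[col]]))
  }

  structure(
    list(n_trials = n_trials, status_counts = status_counts, bins = bins,
         bins_by_sponsor = bins_by_sponsor, tallies = tallies,
         n_binned_current_trend = nrow(ct_tbl), n_binned_design = nrow(de_tbl)),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf("<survey_summary> %d trials\n", x$n_trials))
  cat("Audit status:\n")
  for (i in seq_len(nrow(x$status_counts))) {
    cat(sprintf("  %-14s %d\n", x$status_counts$status[i], x$status_counts$n[i]))
  }
  cat("Conditional-power bins:\n")
  w <- tidyr::pivot_wider(x$bins, names_from = "bin", values_from = "n")
  print(as.data.frame(w), row.names = FALSE)
  invisible(x)
}

#' @rdname summarize_survey
#' @param x A `survey_summary`.
#' @param ... Unused.
#' @method tidy survey_summary
#' @export
tidy.survey_summary <- function(x, ...) x$bins

#' @rdname summarize_survey
#' @method glance survey_summary
#' @export
glance.survey_summary <- function(x, ...) {
  cnt <- setNames(x$status_counts$n, x$status_counts$status)
  tibble(
    n_trials = x$n_trials,
    n_computed = cnt[["computed"]],
    n_reported_only = cnt[["reported_only"]],
    n_insufficient = cnt[["insufficient"]],
    n_binned_current_trend = x$n_binned_current_trend,
    n_binned_design = x$n_binned_design
  )
}
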