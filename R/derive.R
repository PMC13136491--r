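## Derivation of binary IPV outcomes and composite covariates from
## item-level survey responses.
##
## A domain outcome covers the last 12 months: a woman is positive on a
## domain iff at least one of its acts occurred "often" or "sometimes" in
## that window. Lifetime-only reports (ever = yes, 12-month frequency
## "not_at_all") do not count.

#' Derive a binary 12-month IPV domain outcome from act-level items
#'
#' @param ever matrix/data.frame (or vector for one act) of "yes"/"no"
#'   ever-experienced responses, one column per act.
#' @param freq matching 12-month frequency responses with codes
#'   \code{"often"}, \code{"sometimes"}, \code{"not_at_all"} (NA = missing).
#' @return integer vector: 1 if any act occurred in the last 12 months, 0 if
#'   none did, NA when this cannot be determined because items are missing
#'   (such rows are removed by complete-case filtering downstream).
#' @export
derive_domain <- function(ever, freq) {
  ever <- as.matrix(ever)
  freq <- as.matrix(freq)
  if (!all(dim(ever) == dim(freq))) {
    stop("'ever' and 'freq' must have the same shape")
  }
  if (ncol(freq) == 0L) stop("empty item list")
  bad_freq <- !is.na(freq) & !freq %in% freq_codes
  if (any(bad_freq)) {
    stop("unknown frequency code(s): ",
         paste(unique(freq[bad_freq]), collapse = ", "))
  }
  ## an item is missing when neither response is available
  item_missing <- is.na(freq) & is.na(ever)
  pos <- !is.na(freq) & freq %in% c("often", "sometimes")
  any_pos <- rowSums(pos) > 0
  any_miss <- rowSums(item_missing | (is.na(freq) & !is.na(ever) &
                                        ever == "yes")) > 0
  out <- as.integer(any_pos)
  out[!any_pos & any_miss] <- NA_integer_
  out
}

#' Overall IPV indicator
#'
#' @param phys,emo,sex binary domain outcomes.
#' @return logical OR as integer (NA-propagating only when no domain is 1).
#' @export
derive_any_ipv <- function(phys, emo, sex) {
  m <- cbind(phys, emo, sex)
  out <- as.integer(rowSums(m == 1, na.rm = TRUE) > 0)
  out[out == 0 & rowSums(is.na(m)) > 0] <- NA_integer_
  out
}

#' Composite media exposure
#'
#' Positive iff the woman used at least one medium (newspaper/magazine,
#' radio, television) at least once in the reference week.
#'
#' @param newspaper,radio,tv frequency codes among \code{"not_at_all"},
#'   \code{"less_than_once_week"}, \code{"at_least_once_week"}.
#' @return integer 0/1 (NA when indeterminate from missing items).
#' @export
derive_media_exposure <- function(newspaper, radio, tv) {
  m <- cbind(newspaper, radio, tv)
  bad <- !is.na(m) & !m %in% media_codes
  if (any(bad)) {
    stop("unknown media frequency code(s): ",
         paste(unique(m[bad]), collapse = ", "))
  }
  any_weekly <- rowSums(m == "at_least_once_week", na.rm = TRUE) > 0
  out <- as.integer(any_weekly)
  out[!any_weekly & rowSums(is.na(m)) > 0] <- NA_integer_
  out
}

#' Composite attitude towards wife beating
#'
#' Standard DHS convention: a woman holds an accepting ("positive") attitude
#' iff she regards beating as justified in at least one of the presented
#' scenarios.
#'
#' @param scenarios matrix/data.frame of "yes"/"no" responses, one column
#'   per scenario.
#' @return integer 0/1 (NA when indeterminate from missing items).
#' @export
derive_attitude_wife_beating <- function(scenarios) {
  m <- as.matrix(scenarios)
  if (ncol(m) == 0L) stop("at least one scenario is required")
  bad <- !is.na(m) & !m %in% c("yes", "no")
  if (any(bad)) {
    stop("unknown attitude code(s): ", paste(unique(m[bad]), collapse = ", "))
  }
  any_yes <- rowSums(m == "yes", na.rm = TRUE) > 0
  out <- as.integer(any_yes)
  out[!any_yes & rowSums(is.na(m)) > 0] <- NA_integer_
  out
}

#' Composite decision-making autonomy
#'
#' Standard DHS convention: a woman has decision-making autonomy iff she
#' participates (alone or jointly) in every supplied household decision.
#'
#' @param decisions matrix/data.frame of codes \code{"self"},
#'   \code{"joint"}, \code{"other"}, one column per decision item.
#' @return integer 0/1 (NA when indeterminate from missing items).
#' @export
derive_decision_autonomy <- function(decisions) {
  m <- as.matrix(decisions)
  if (ncol(m) == 0L) stop("at least one decision item is required")
  bad <- !is.na(m) & !m %in% decision_codes
  if (any(bad)) {
    stop("unknown decision code(s): ", paste(unique(m[bad]), collapse = ", "))
  }
  any_other <- rowSums(m == "other", na.rm = TRUE) > 0
  part <- matrix(m %in% c("self", "joint"), nrow = nrow(m))
  all_part <- rowSums(part) == ncol(m)
  out <- integer(nrow(m))
  out[all_part] <- 1L
  out[!all_part & !any_other] <- NA_integer_
  out
}

#' Dummy-code categorical covariates with reference levels dropped
#'
#' @param covs data.frame of covariate columns holding level codes.
#' @param factors level definitions (\code{\link{ipv_factors}}); the first
#'   level of each factor is the dropped reference.
#' @return numeric matrix with columns \code{"<factor>.<level>"}.
#' @export
dummy_matrix <- function(covs, factors = ipv_factors()) {
  fs <- intersect(names(factors), names(covs))
  cols <- lapply(fs, function(f) {
    x <- covs[[f]]
    bad <- !is.na(x) & !x %in% factors[[f]]
    if (any(bad)) {
      stop("unknown category code(s) in '", f, "': ",
           paste(unique(x[bad]), collapse = ", "))
    }
    m <- sapply(factors[[f]][-1L], function(l) as.numeric(x == l))
    m <- matrix(m, nrow = length(x))
    colnames(m) <- dummy_names(f, factors[[f]])
    m
  })
  do.call(cbind, cols)
}

#' Default mapping from raw column names to analysis variables
#'
#' Matches the column layout written by \code{\link{simulate_population}};
#' supply a modified copy (or a YAML file read with
#' \code{yaml::read_yaml}) to use other source columns.
#'
#' @return nested named list.
#' @export
default_column_map <- function() {
  acts <- ipv_act_items()
  prefix <- c(physical = "phys", emotional = "emo", sexual = "sex")
  list(
    design = c(country = "country_id", stratum = "stratum_id",
               psu = "psu_id", weight = "weight"),
    indicators = setNames(paste0("hcb_", hcb_indicators()), hcb_indicators()),
    acts = lapply(names(acts), function(d) {
      list(ever = paste0(prefix[[d]], "_", acts[[d]], "_ever"),
           freq = paste0(prefix[[d]], "_", acts[[d]], "_freq"))
    }) |> setNames(names(acts)),
    media = c(newspaper = "media_newspaper", radio = "media_radio",
              tv = "media_tv"),
    decisions = setNames(decision_items, decision_items),
    attitude = setNames(attitude_items, attitude_items),
    covariates = c(age_group = "age_group", residence = "residence",
                   education = "education", wealth = "wealth",
                   working = "working", pregnant = "pregnant",
                   smoking = "smoking",
                   husband_education = "husband_education",
                   husband_working = "husband_working",
                   husband_alcohol = "husband_alcohol")
  )
}

check_mapped <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("mapped ", what, " column(s) not found in input: ",
         paste(missing, collapse = ", "))
  }
}

#' Build the complete-case analysis table
#'
#' Derives the three binary 12-month IPV domains, overall IPV, and the
#' composite covariates (media exposure, decision-making autonomy, attitude
#' towards wife beating) from item-level columns, attaches indicator items
#' and design columns, and removes every row with a missing value on any
#' analysis variable (strict complete-case, no imputation).
#'
#' @param records woman-level data.frame of raw columns.
#' @param mapping column mapping, see \code{\link{default_column_map}}.
#' @param factors covariate level definitions.
#' @return data.frame of class \code{ipv_data} with columns \code{country},
#'   \code{stratum}, \code{psu}, \code{weight}, outcomes
#'   \code{phys_ipv}/\code{emo_ipv}/\code{sex_ipv}/\code{any_ipv}, one
#'   binary column per indicator item and one factor column per covariate;
#'   attribute \code{"removal_log"} records row counts dropped per reason.
#' @export
build_analysis_table <- function(records, mapping = default_column_map(),
                                 factors = ipv_factors()) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  check_mapped(records, unlist(mapping$design), "design")
  check_mapped(records, unlist(mapping$indicators), "indicator")
  check_mapped(records, unlist(mapping$acts), "act item")
  check_mapped(records, unlist(mapping$media), "media item")
  check_mapped(records, unlist(mapping$decisions), "decision item")
  check_mapped(records, unlist(mapping$attitude), "attitude item")
  check_mapped(records, unlist(mapping$covariates), "covariate")

  out <- data.frame(
    country = records[[mapping$design[["country"]]]],
    stratum = records[[mapping$design[["stratum"]]]],
    psu = records[[mapping$design[["psu"]]]],
    weight = records[[mapping$design[["weight"]]]]
  )
  if (any(is.na(out$weight)) || any(out$weight <= 0, na.rm = TRUE)) {
    stop("weights must be present and positive")
  }

  dom <- list(physical = "phys_ipv", emotional = "emo_ipv",
              sexual = "sex_ipv")
  for (d in names(dom)) {
    out[[dom[[d]]]] <- derive_domain(records[mapping$acts[[d]]$ever],
                                     records[mapping$acts[[d]]$freq])
  }
  out$any_ipv <- derive_any_ipv(out$phys_ipv, out$emo_ipv, out$sex_ipv)

  for (ind in names(mapping$indicators)) {
    v <- records[[mapping$indicators[[ind]]]]
    if (!all(v %in% c(0, 1, NA))) {
      stop("indicator '", ind, "' is not binary 0/1")
    }
    out[[ind]] <- as.integer(v)
  }

  covs <- data.frame(row.names = seq_len(nrow(records)))
  for (f in names(mapping$covariates)) {
    covs[[f]] <- records[[mapping$covariates[[f]]]]
  }
  covs$media_exposure <- c("no", "yes")[
    1 + derive_media_exposure(records[[mapping$media[["newspaper"]]]],
                              records[[mapping$media[["radio"]]]],
                              records[[mapping$media[["tv"]]]])]
  covs$autonomy <- c("no", "yes")[
    1 + derive_decision_autonomy(records[unlist(mapping$decisions)])]
  covs$beating_attitude <- c("no", "yes")[
    1 + derive_attitude_wife_beating(records[unlist(mapping$attitude)])]

  ## validate codes (errors on unknown categories) before filtering
  invisible(dummy_matrix(covs, factors))

  for (f in intersect(names(factors), names(covs))) {
    out[[f]] <- factor(covs[[f]], levels = factors[[f]])
  }

  keep <- stats::complete.cases(out)
  log <- c(input_rows = nrow(out),
           removed_missing = sum(!keep),
           retained = sum(keep))
  if (!any(keep)) stop("no complete-case rows remain after filtering")
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "removal_log") <- log
  attr(res, "factors") <- factors
  class(res) <- c("ipv_data", "data.frame")
  res
}
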