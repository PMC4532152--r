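#' Age-sex strata
#'
#' The accounting and projection stages stratify the population into
#' 5-year age bands (`"15-19"`, ..., `"80-84"`, `"85+"`) crossed with
#' sex.  Band labels are plain strings; [age_band_lower()] parses the
#' numeric lower bound used for working-age decisions.
#'
#' @name strata
NULL

#' Default 5-year age bands from 15 to 85+
#'
#' @param from lower bound of the first band (default 15).
#' @param to lower bound of the open top band (default 85).
#' @param width band width in years (default 5).
#' @return character vector of band labels, e.g. `"15-19"` ... `"85+"`.
#' @export
#' @examples
#' default_age_groups()
default_age_groups <- function(from = 15, to = 85, width = 5) {
  lowers <- seq(from, to - width, by = width)
  c(sprintf("%d-%d", lowers, lowers + width - 1), sprintf("%d+", to))
}

#' Parse the lower bound of an age-band label
#'
#' @param labels character vector such as `"60-64"` or `"85+"`.
#' @return integer vector of lower bounds.
#' @export
#' @examples
#' age_band_lower(c("15-19", "85+"))
age_band_lower <- function(labels) {
  m <- regmatches(labels, regexpr("^[0-9]+", labels))
  ok <- lengths(regmatches(labels, gregexpr("^[0-9]+(-[0-9]+|\\+)$", labels))) == 1
  if (!all(ok)) {
    abort("field 'age_group': cannot parse label(s): %s",
          paste(unique(labels[!ok]), collapse = ", "))
  }
  as.integer(m)
}

#' Check that age bands partition an age range without gaps or overlap
#'
#' @param labels character vector of band labels.
#' @param from expected lower bound of the first band.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_age_groups <- function(labels, from = 15) {
  labels <- unique(labels)
  lo <- age_band_lower(labels)
  o <- order(lo)
  labels <- labels[o]; lo <- lo[o]
  n <- length(labels)
  if (lo[1] != from) {
    abort("field 'age_group': first band starts at %d, expected %d", lo[1], from)
  }
  if (!grepl("\\+$", labels[n])) {
    abort("field 'age_group': top band must be open (e.g. '85+')")
  }
  closed <- labels[-n]
  if (any(grepl("\\+$", closed))) {
    abort("field 'age_group': only the top band may be open")
  }
  hi <- as.integer(sub("^[0-9]+-", "", closed))
  if (any(hi + 1L != lo[-1])) {
    abort("field 'age_group': bands do not partition ages without gaps/overlap")
  }
  invisible(TRUE)
}

#' Working-age indicator for an age band
#'
#' Indirect (productivity) costs are only attributed to strata whose
#' band lower bound is below the retirement age: morbidity in already
#' retired age groups causes no productivity loss.
#'
#' @param age_group character vector of band labels.
#' @param retirement_age retirement age in years (default 65).
#' @return logical vector.
#' @export
#' @examples
#' is_working_age(c("60-64", "65-69", "85+"))
is_working_age <- function(age_group, retirement_age = 65) {
  age_band_lower(age_group) < retirement_age
}

## canonical stratum ordering used everywhere randomness is drawn
stratum_order <- function(dt) {
  dt[order(age_band_lower(age_group), sex)]
}

#' Cross age bands with sexes
#'
#' @param age_groups character vector of band labels.
#' @param sexes character vector (default `c("female", "male")`).
#' @return a `data.table` with columns `age_group`, `sex`.
#' @export
make_strata <- function(age_groups = default_age_groups(),
                        sexes = c("female", "male")) {
  stratum_order(data.table::CJ(age_group = age_groups, sex = sexes))
}
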