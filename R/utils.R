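#' @keywords internal
"_PACKAGE"

## Typed conditions so callers can distinguish configuration mistakes from
## malformed inputs or schedule inconsistencies.
ec_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "ec_error", "error")))
}

ec_config_error   <- function(fmt, ...) ec_stop("ec_config_error", fmt, ...)
ec_input_error    <- function(fmt, ...) ec_stop("ec_input_error", fmt, ...)
ec_schedule_error <- function(fmt, ...) ec_stop("ec_schedule_error", fmt, ...)

ec_warn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "ec_warning", "warning")))
}

## Condition label helpers. Labels follow the convention
## <modality>CS_<pairing>[_<box>], e.g. "ACS_US", "VCS_ALONE", "ACS_US_B2".
is_paired_label <- function(x) !grepl("ALONE", x)

#' Collapse four-way condition labels onto a binary dimension
#'
#' `"relational"` groups trials by pairing (CS-alone vs CS-US blocks),
#' `"physical"` by CS modality (auditory vs visual), `"box"` by conditioning
#' chamber (labels carrying a `_B<k>` suffix).
#'
#' @param labels character or factor of condition labels such as `"ACS_US"`.
#' @param dimension one of `"relational"`, `"physical"`, `"box"`.
#' @return factor with two levels.
#' @export
collapse_labels <- function(labels,
                            dimension = c("relational", "physical", "box")) {
  dimension <- match.arg(dimension)
  labels <- as.character(labels)
  out <- switch(dimension,
    relational = ifelse(grepl("ALONE", labels), "ALONE", "PAIRED"),
    physical   = substr(labels, 1L, 3L),
    box        = {
      m <- regmatches(labels, regexpr("B[0-9]+$", labels))
      if (length(m) != length(labels))
        ec_config_error("box collapse requires labels with a _B<k> suffix")
      m
    })
  factor(out)
}

## Half-open window membership: a ∈ [lo, hi).
in_window <- function(x, lo, hi) x >= lo & x < hi

## Draw a sub-seed for an independent RNG stream, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 1013904223L + k * 69069L) %% 2147483647L
}
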