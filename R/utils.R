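# Instrument metadata shared by validation, I/O and the simulator.
# lo/hi are hard range limits (NA = unbounded); lo_open marks ranges that
# exclude the lower bound (serum IgG must be strictly positive).
star_instruments <- function() {
  tibble::tribble(
    ~instrument,   ~domain,       ~lo, ~hi, ~lo_open, ~direction,
    "clin_essdai", "systemic",      0,  NA, FALSE,    "decrease",
    "esspri",      "pro",           0,  10, FALSE,    "decrease",
    "schirmer",    "lachrymal",     0,  NA, FALSE,    "increase",
    "oss",         "lachrymal",     0,  12, FALSE,    "decrease",
    "uwsf",        "salivary",      0,  NA, FALSE,    "increase",
    "hocevar",     "salivary",      0,  48, FALSE,    "decrease",
    "igg",         "biological",    0,  NA, TRUE,     "decrease",
    "rf",          "biological",    0,  NA, FALSE,    "decrease"
  )
}

star_domains <- function() c("systemic", "pro", "lachrymal", "salivary", "biological")

# Point weights: two major domains (systemic activity, patient-reported
# outcome) carry 3 points each, the three glandular/biological minors 1 each.
star_domain_weights <- function() {
  c(systemic = 3, pro = 3, lachrymal = 1, salivary = 1, biological = 1)
}

measurement_columns <- function() {
  inst <- star_instruments()$instrument
  c(paste0(inst, "_base"), paste0(inst, "_fu"))
}

tri_levels <- c("yes", "no", "undetermined")

tri_state <- function(x) factor(x, levels = tri_levels)

tri_yes <- function(x) !is.na(x) & x == "yes"

# Validate one instrument's values against its range; `where` names the
# context (column, operation) for error messages.
check_instrument_range <- function(x, instrument, where = instrument) {
  meta <- dplyr::filter(star_instruments(), .data$instrument == !!instrument)
  bad <- rep(FALSE, length(x))
  ok <- !is.na(x)
  if (!is.na(meta$lo)) {
    bad[ok] <- bad[ok] | (if (meta$lo_open) x[ok] <= meta$lo else x[ok] < meta$lo)
  }
  if (!is.na(meta$hi)) bad[ok] <- bad[ok] | x[ok] > meta$hi
  if (any(bad)) {
    rng <- paste0(if (meta$lo_open) "(" else "[", meta$lo, ", ",
                  if (is.na(meta$hi)) "Inf)" else paste0(meta$hi, "]"))
    abort(sprintf("%s: value(s) %s outside allowed range %s",
                  where, paste(unique(x[bad]), collapse = ", "), rng),
          class = "sjstar_validation_error")
  }
  invisible(x)
}

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
          class = "sjstar_validation_error")
  }
  invisible(x)
}
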