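# internal helpers

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# classed conditions so callers can distinguish failure modes
pep_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pepscanr_error", "error", "condition"),
                      call = call))
}

pep_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "pepscanr_warning", "warning", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_int <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    pep_stop(sprintf("`%s` must be a single integer >= %s", name, min), "bad_argument")
  as.integer(x)
}

fmt_pct <- function(num, den) {
  # whole-number percentages, as reported in cohort tables: 53/59 -> "90%"
  sprintf("%d%%", as.integer(round(100 * num / den)))
}
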