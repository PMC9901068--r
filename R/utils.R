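# Internal validation helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

check_fraction <- function(x, name) {
  stop_if_not(is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1,
              sprintf("'%s' must be a single value in [0, 1]", name))
}

check_count <- function(x, name, min = 1L) {
  stop_if_not(is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min &&
                x == round(x),
              sprintf("'%s' must be an integer >= %d", name, min))
}

check_positive <- function(x, name) {
  stop_if_not(is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0,
              sprintf("'%s' must be a single positive value", name))
}

# Unit identifier for a (gene, panel) pair; used throughout clumping.
unit_id <- function(gene_id, panel_id) paste(gene_id, panel_id, sep = "::")

# Deterministic per-stage seeding so each generator is a pure function of
# (config, seed) regardless of call order. Offsets are fixed per stage.
stage_seed <- function(seed, offset) {
  (as.integer(seed) %% 1048576L) * 1009L + as.integer(offset)
}
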