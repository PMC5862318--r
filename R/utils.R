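# Internal helpers shared across modules.

# Derive a reproducible 32-bit substream seed from a base seed and a
# character key. All randomness in the package flows from one run seed
# through named substreams so stages can be re-run independently.
substream <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  codes <- utf8ToInt(key)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 1048573) * 2048 + h %% 2048) %% 2147483629L
}

with_stream <- function(seed, ..., code) {
  withr::with_seed(substream(seed, ...), code)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  x
}

# Column-name conventions for the indicator hierarchy.
is_class_col <- function(x) startsWith(x, "cls_")
is_group_col <- function(x) startsWith(x, "grp_")
is_generic_col <- function(x) startsWith(x, "gen_")
is_maintenance_col <- function(x) startsWith(x, "mnt_")
is_indicator_col <- function(x) {
  is_class_col(x) | is_group_col(x) | is_generic_col(x) | is_maintenance_col(x)
}

indicator_columns <- function(data) {
  names(data)[is_indicator_col(names(data))]
}
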