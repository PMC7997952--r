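# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# require columns on a data frame, with a caller-facing error
check_columns <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# coerce a groups argument (tibble with genome_id/group, or named vector)
# to a named character vector keyed by genome_id
as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    check_columns(groups, c("genome_id", "group"), "groups")
    setNames(as.character(groups$group), as.character(groups$genome_id))
  } else if (!is.null(names(groups))) {
    setNames(as.character(groups), names(groups))
  } else {
    abort("`groups` must be a data frame with genome_id/group or a named vector")
  }
}

# canonical unordered pair: a < b lexicographically
canonical_pair <- function(a, b) {
  swap <- a > b
  tibble(seq_a = ifelse(swap, b, a), seq_b = ifelse(swap, a, b))
}
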