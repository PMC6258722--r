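# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic per-stage sub-seed from a global seed and a stage
# label, so each pipeline stage consumes an independent reproducible stream.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  h <- sum(as.double(utf8ToInt(stage)) * seq_along(utf8ToInt(stage)) * 131)
  s <- (abs(as.double(seed)) * 48271 + h * 7919) %% 2147483587
  as.integer(s) + 1L
}

# Zero-padded identifier factory: ids sort lexicographically in numeric order.
make_ids <- function(prefix, n, width = 6L) {
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}

stop_stage <- function(stage, e) {
  abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# A wide id + per-sample table (first column the id) -> numeric matrix.
panel_matrix <- function(tbl, id_col) {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- tbl[[id_col]]
  m
}
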