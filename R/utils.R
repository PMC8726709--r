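# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the
# caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-sample seed from a global seed, staying inside the
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 131L + index * 7919) %% 2147483641)
}

# Classed conditions so callers (notably the command-line wrapper) can
# distinguish configuration problems from malformed data.
config_error <- function(msg) {
  stop(structure(class = c("contamtrace_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

format_error <- function(msg) {
  stop(structure(class = c("contamtrace_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
  }
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
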