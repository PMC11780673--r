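# Internal helpers shared across modules.

# The six clinical signs of the feline chronic enteropathy consensus panel,
# in the fixed order they are asked.
default_signs <- function() {
  c("decreased appetite", "vomiting", "weight loss",
    "diarrhea", "constipation", "polyphagia")
}

# Critical value for a two-sided confidence level.
z_from_level <- function(conf_level) {
  stopifnot(is.numeric(conf_level), length(conf_level) == 1L,
            conf_level > 0, conf_level < 1)
  qnorm(1 - (1 - conf_level) / 2)
}

# Verdicts are logical vectors; NA is the third state ("NA" answer).
as_verdict <- function(x) {
  if (is.logical(x)) return(x)
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[lx %in% c("true", "t")] <- TRUE
    out[lx %in% c("false", "f")] <- FALSE
    return(as.logical(out))
  }
  as.logical(x)
}

# Case-folded, punctuation-stripped whitespace tokens (citation matching).
fold_tokens <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Whitespace tokens of a string (word counting).
count_words <- function(x) {
  vapply(strsplit(trimws(x), "[[:space:]]+"),
         function(t) sum(nzchar(t)), integer(1))
}

# Deterministic child seeds: one master seed fans out to named stages so each
# stage is independently reproducible. Kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    all(if (open_left) x > 0 else x >= 0) &&
    all(if (open_right) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be %s finite proportion%s in %s",
                  name, if (length(x) > 1) "a vector of" else "a",
                  if (length(x) > 1) "s" else "",
                  paste0(if (open_left) "(" else "[", "0,1",
                         if (open_right) ")" else "]")),
          class = "ehrsigneval_validation_error")
  }
  invisible(x)
}
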