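#' Construct a token sequence
#'
#' The universal input container: an ordered sequence of symbolic tokens.
#' Token identifiers are opaque — character strings for corpus data, integer
#' creation-order labels for model-generated sequences. All downstream
#' analyses depend only on token positions and frequencies, never on the
#' labels themselves.
#'
#' @param tokens character or integer vector of token identifiers, in
#'   sequence order. Must be non-empty and contain no empty strings or NAs.
#' @return An object of class `token_sequence`: a list with elements
#'   `tokens` and `M` (the sequence length).
#' @examples
#' token_sequence(c("to", "be", "or", "not", "to", "be"))
#' @export
token_sequence <- function(tokens) {
  if (is.factor(tokens)) tokens <- as.character(tokens)
  if (!is.character(tokens) && !is.numeric(tokens)) {
    stop("tokens must be a character or integer vector")
  }
  if (length(tokens) == 0L) stop("empty sequence")
  if (anyNA(tokens)) stop("tokens must not contain NA")
  if (is.character(tokens) && any(!nzchar(tokens))) {
    stop("token identifiers must be non-empty")
  }
  if (is.numeric(tokens)) storage.mode(tokens) <- "integer"
  structure(list(tokens = tokens, M = length(tokens)),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  n_show <- min(8L, x$M)
  shown <- paste(utils::head(x$tokens, n_show), collapse = " ")
  if (x$M > n_show) shown <- paste(shown, "...")
  cat(sprintf("<token_sequence> M = %d tokens, %d types\n  %s\n",
              x$M, length(unique(x$tokens)), shown))
  invisible(x)
}

#' @export
length.token_sequence <- function(x) x$M

# Integer codes in first-occurrence order, shared by intervals and scaling.
token_ids <- function(seq) {
  match(seq$tokens, unique(seq$tokens))
}

as_token_sequence <- function(x) {
  if (inherits(x, "token_sequence")) x else token_sequence(x)
}

#' Tokenize raw text into a token sequence
#'
#' Splits text on whitespace. By default, punctuation is stripped from token
#' edges (internal punctuation such as apostrophes is kept) and tokens are
#' lowercased, so `"Art thou?"` yields tokens `art`, `thou`. Tokens that are
#' empty after stripping (isolated punctuation) are dropped.
#'
#' @param text character vector (elements are concatenated with spaces) or a
#'   connection/file path is not accepted here — see [read_tokens()] for
#'   token-stream files.
#' @param lowercase lowercase tokens? Default `TRUE`.
#' @param strip_punct strip leading/trailing punctuation? Default `TRUE`.
#' @return A [token_sequence()].
#' @examples
#' tokenize_text("Oh Romeo Romeo wherefore art thou Romeo")$M # 7
#' @export
tokenize_text <- function(text, lowercase = TRUE, strip_punct = TRUE) {
  stopifnot(is.character(text))
  raw <- unlist(strsplit(paste(text, collapse = " "), "[[:space:]]+"))
  raw <- raw[nzchar(raw)]
  if (strip_punct) {
    raw <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", raw)
    raw <- raw[nzchar(raw)]
  }
  if (lowercase) raw <- tolower(raw)
  if (length(raw) == 0L) stop("empty sequence")
  token_sequence(raw)
}

#' Speaker/code filter for CHAT transcripts
#'
#' @param include_speakers character vector of speaker codes whose main-tier
#'   utterances are kept (e.g., `"CHI"` for the child tier). Must be
#'   non-empty.
#' @param drop_tokens character vector of code tokens removed from the
#'   output before counting, e.g. the conventional unknown-word codes.
#' @return An object of class `chat_filter`.
#' @export
chat_filter <- function(include_speakers,
                        drop_tokens = c("xxx", "yyy", "www")) {
  include_speakers <- toupper(as.character(include_speakers))
  if (length(include_speakers) == 0L) {
    stop("include_speakers must be non-empty")
  }
  structure(list(include_speakers = include_speakers,
                 drop_tokens = as.character(drop_tokens)),
            class = "chat_filter")
}

#' Read CHAT transcript files with speaker filtering
#'
#' A minimal CHAT reader: only main tiers (`*SPK:\tutterance`) are parsed;
#' header (`@`) and dependent (`%`) tiers are ignored, and continuation
#' lines (starting with whitespace) are appended to the current tier.
#' Utterances of the included speakers are concatenated in file order, then
#' utterance order, tokenized with [tokenize_text()] defaults, and any
#' token listed in `filter$drop_tokens` is removed before `M` is counted.
#'
#' @param paths character vector of `.cha` file paths, read in order.
#' @param filter a [chat_filter()].
#' @param lowercase,strip_punct passed to the tokenizer.
#' @return A [token_sequence()] of the retained speakers' tokens.
#' @export
read_chat <- function(paths, filter, lowercase = TRUE, strip_punct = TRUE) {
  stopifnot(inherits(filter, "chat_filter"))
  utterances <- character(0)
  for (path in paths) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    current_speaker <- NA_character_
    for (line in lines) {
      if (grepl("^\\*", line)) {
        m <- regmatches(line, regexec("^\\*([^:]+):[[:space:]]*(.*)$", line))[[1]]
        if (length(m) == 3L) {
          current_speaker <- toupper(m[2])
          if (current_speaker %in% filter$include_speakers) {
            utterances <- c(utterances, m[3])
          }
        } else {
          current_speaker <- NA_character_
        }
      } else if (grepl("^[[:space:]]", line) && !is.na(current_speaker)) {
        if (current_speaker %in% filter$include_speakers) {
          utterances[length(utterances)] <-
            paste(utterances[length(utterances)], trimws(line))
        }
      } else {
        current_speaker <- NA_character_
      }
    }
  }
  if (length(utterances) == 0L) {
    stop("no utterance from any included speaker")
  }
  seq <- tokenize_text(paste(utterances, collapse = " "),
                       lowercase = lowercase, strip_punct = strip_punct)
  drop <- if (lowercase) tolower(filter$drop_tokens) else filter$drop_tokens
  kept <- seq$tokens[!(seq$tokens %in% drop)]
  if (length(kept) == 0L) stop("no tokens left after code removal")
  token_sequence(kept)
}

#' Read and write token-stream files
#'
#' Token-stream files hold one token per line (UTF-8), which is unambiguous
#' even for tokens containing internal punctuation. `write_tokens()` then
#' `read_tokens()` is the identity on token sequences. Blank lines are
#' skipped with a warning on read.
#'
#' @param path file path.
#' @return `read_tokens()` returns a [token_sequence()]; `write_tokens()`
#'   returns `path` invisibly.
#' @export
read_tokens <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sprintf("skipped %d blank line(s) in %s", sum(blank), path))
    lines <- lines[!blank]
  }
  if (length(lines) == 0L) stop("empty sequence")
  token_sequence(lines)
}

#' @param seq a [token_sequence()].
#' @rdname read_tokens
#' @export
write_tokens <- function(seq, path) {
  seq <- as_token_sequence(seq)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(as.character(seq$tokens), con)
  invisible(path)
}
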