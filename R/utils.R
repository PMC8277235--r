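# Internal helpers shared across modules.
# Character offsets are 0-based, end-exclusive throughout (BRAT convention);
# they count Unicode code points, which is what substr()/nchar() count on
# UTF-8 strings in R.

span_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

#' @noRd
escape_regex <- function(x) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
}

# Word tokenization with character offsets. Tokens are alphanumeric runs;
# hyphens and apostrophes inside a word are literal parts of it.
tokenize <- function(text) {
  m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*", text, perl = TRUE)[[1]]
  if (length(m) == 1L && m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = as.integer(m) - 1L,
             end   = as.integer(m) + len - 1L,
             stringsAsFactors = FALSE)
}

# Case-insensitive, whole-word, longest-match-first, non-overlapping
# dictionary matching. `terms` is a character vector of surface terms;
# internal whitespace in a term matches any whitespace run.
# Returns a data.frame(term, start, end, text) sorted by start.
match_terms <- function(text, terms) {
  empty <- data.frame(term = character(), start = integer(), end = integer(),
                      text = character(), stringsAsFactors = FALSE)
  if (!nzchar(text) || length(terms) == 0L) return(empty)
  terms <- unique(terms[nzchar(terms)])
  ord <- order(-nchar(terms), terms)
  occupied <- rep(FALSE, nchar(text))
  out <- vector("list", length(terms))
  k <- 0L
  for (term in terms[ord]) {
    pat <- gsub("[[:space:]]+", "[[:space:]]+", escape_regex(term))
    pat <- paste0("(?<![[:alnum:]])", pat, "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      s <- as.integer(m[i])          # 1-based start
      e <- s + len[i] - 1L           # 1-based end (inclusive)
      if (any(occupied[s:e])) next   # longer terms claimed this region first
      occupied[s:e] <- TRUE
      k <- k + 1L
      out[[k]] <- data.frame(term = term, start = s - 1L, end = e,
                             text = substr(text, s, e),
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res[order(res$start), , drop = FALSE]
}

# Length of the overlap of [a1,a2) and [b1,b2).
overlap_length <- function(a1, a2, b1, b2) {
  pmax(0L, pmin(a2, b2) - pmax(a1, b1))
}

# Maximum-cardinality bipartite matching (Kuhn's augmenting paths) on an
# adjacency list: adj[[u]] = candidate right-side partners of left node u,
# ordered by preference (largest overlap first, so ties resolve toward the
# strongest alignment). Returns integer vector match_right (0 = unmatched).
kuhn_matching <- function(adj, n_right) {
  match_right <- integer(n_right)
  n_left <- length(adj)
  seen <- logical(n_right)
  try_augment <- function(u) {
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <<- TRUE
        if (match_right[v] == 0L || try_augment(match_right[v])) {
          match_right[v] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (u in seq_len(n_left)) {
    seen[] <- FALSE
    try_augment(u)
  }
  match_right
}

`%||%` <- function(a, b) if (is.null(a)) b else a
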