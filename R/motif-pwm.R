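#' Position weight matrices and log-odds scanning
#'
#' A `motif_pwm` is a per-position base-probability matrix with a background
#' base-frequency model and a log-odds score threshold. Scanning scores a
#' window as `sum log2(p[pos, base] / bg[base])`; a window is a hit when its
#' score reaches the threshold, on either strand. `N` bases contribute zero
#' (they score as background).
#'
#' @param matrix numeric matrix, positions x 4, columns `A,C,G,T`; each row
#'   must sum to 1.
#' @param name motif name.
#' @param background length-4 base frequencies summing to 1 (default
#'   uniform).
#' @param threshold log-odds hit threshold in bits; default 80% of the
#'   motif's maximum achievable score.
#' @return an object of class `motif_pwm`.
#' @export
motif_pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                      threshold = NULL) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, length(background) == 4)
  colnames(matrix) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("each PWM position's probabilities must sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  names(background) <- c("A", "C", "G", "T")
  obj <- structure(list(name = name, matrix = matrix,
                        background = background),
                   class = "motif_pwm")
  if (is.null(threshold)) threshold <- 0.8 * max_score(obj)
  obj$threshold <- threshold
  obj
}

#' @export
print.motif_pwm <- function(x, ...) {
  cat(sprintf("motif_pwm '%s': %d positions, consensus %s, threshold %.2f bits\n",
              x$name, nrow(x$matrix), consensus(x), x$threshold))
  invisible(x)
}

## log2-odds matrix with a probability floor so zero entries stay finite
logodds_matrix <- function(pwm, floor = 1e-4) {
  log2(pmax(pwm$matrix, floor) / rep(pwm$background, each = nrow(pwm$matrix)))
}

#' @rdname motif_pwm
#' @param pwm a `motif_pwm`.
#' @export
max_score <- function(pwm) sum(apply(logodds_matrix(pwm), 1, max))

#' @rdname motif_pwm
#' @export
consensus <- function(pwm) {
  paste(c("A", "C", "G", "T")[apply(pwm$matrix, 1, which.max)],
        collapse = "")
}

#' Near-deterministic PWM from a consensus string
#'
#' Utility for planting and testing: the consensus base gets probability
#' `p` at each position, the other three split the remainder equally.
#'
#' @param sequence consensus string over `{A,C,G,T}`.
#' @param name motif name.
#' @param p consensus-base probability per position.
#' @param ... passed to [motif_pwm()].
#' @export
consensus_pwm <- function(sequence, name = sequence, p = 1, ...) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(all(bases %in% c("A", "C", "G", "T")))
  m <- matrix((1 - p) / 3, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))] <- p
  motif_pwm(m, name = name, ...)
}

reverse_complement_pwm <- function(pwm) {
  m <- pwm$matrix[rev(seq_len(nrow(pwm$matrix))), rev(seq_len(4)),
                  drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  motif_pwm(m, name = pwm$name, background = unname(pwm$background),
            threshold = pwm$threshold)
}

## Per-start-position log-odds scores of one strand. Codes the sequence as
## 1..4 (N and anything else -> 0, scoring 0 bits) and accumulates one
## shifted lookup per motif position, so the scan is vectorised over starts.
scan_scores <- function(seq_chars, lom) {
  m <- nrow(lom)
  L <- length(seq_chars)
  if (L < m) return(numeric(0))
  code <- match(seq_chars, c("A", "C", "G", "T"), nomatch = 0L)
  n_pos <- L - m + 1L
  scores <- numeric(n_pos)
  for (j in seq_len(m)) {
    cj <- code[j:(j + n_pos - 1L)]
    hit <- cj > 0L
    scores[hit] <- scores[hit] + lom[j, cj[hit]]
  }
  scores
}

#' Scan a sequence for PWM hits on both strands
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   `{A,C,G,T,N}`.
#' @param pwm a [motif_pwm()].
#' @param threshold log-odds hit threshold; defaults to the PWM's own.
#' @return data.frame with `start` (1-based position of the hit's leftmost
#'   base on the forward strand), `strand` and `score`; zero rows when the
#'   motif is longer than the sequence.
#' @export
scan_pwm <- function(sequence, pwm, threshold = pwm$threshold) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  lom_f <- logodds_matrix(pwm)
  lom_r <- logodds_matrix(reverse_complement_pwm(pwm))
  sf <- scan_scores(chars, lom_f)
  sr <- scan_scores(chars, lom_r)
  hf <- which(sf >= threshold)
  hr <- which(sr >= threshold)
  out <- data.frame(
    start = c(hf, hr),
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    score = c(sf[hf], sr[hr]))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Read PWMs from JASPAR-style PFM text
#'
#' Accepts the four-row `A [ ... ]` count layout under `>ID name` headers;
#' counts are column-normalised to probabilities.
#'
#' @param path file path.
#' @param ... passed to [motif_pwm()] (e.g. `background`).
#' @return named list of [motif_pwm()].
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' headers found in ", path)
  out <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      as.numeric(strsplit(gsub("[\\[\\]]", " ", l, perl = TRUE),
                          "\\s+")[[1]] |> (\(x) x[nzchar(x)])())
    })
    base_order <- toupper(substr(trimws(block), 1, 1))
    cnt <- do.call(rbind, rows)
    rownames(cnt) <- base_order
    cnt <- cnt[c("A", "C", "G", "T"), , drop = FALSE]
    prob <- t(cnt) / colSums(cnt)
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]]
    motif_pwm(prob, name = name[length(name)], ...)
  })
  stats::setNames(out, vapply(out, function(p) p$name, character(1)))
}

#' Read PWMs from MEME minimal-format text
#' @param path file path.
#' @param ... passed to [motif_pwm()].
#' @return named list of [motif_pwm()].
#' @export
read_meme <- function(path, ...) {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\s", lines)
  if (length(idx) == 0) stop("no MOTIF blocks found in ", path)
  out <- lapply(idx, function(i) {
    name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i + 1L
    while (j <= length(lines) &&
           !grepl("letter-probability matrix", lines[j])) j <- j + 1L
    if (j > length(lines)) stop("MOTIF ", name, " has no probability matrix")
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[j])
    w <- suppressWarnings(as.integer(w))
    rows <- list(); j <- j + 1L
    while (j <= length(lines) && nzchar(trimws(lines[j])) &&
           grepl("^[0-9.eE+\\s-]+$", trimws(lines[j]), perl = TRUE)) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1L
    }
    m <- do.call(rbind, rows)
    if (!is.na(w) && nrow(m) != w)
      stop("MOTIF ", name, ": expected ", w, " rows, found ", nrow(m))
    motif_pwm(m / rowSums(m), name = name, ...)
  })
  stats::setNames(out, vapply(out, function(p) p$name, character(1)))
}
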