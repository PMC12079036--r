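#' Read a multi-rater ratings table from CSV
#'
#' Ratings CSV format: a `segment_id` column followed by one binary column
#' per rater (any column names; `rater_1`, ..., `rater_r` by convention).
#'
#' @param path Path to a ratings CSV file.
#' @return A ratings tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  ratings <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ratings(ratings)
}

#' Write a multi-rater ratings table to CSV
#'
#' @param ratings A ratings tibble (see [read_ratings()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  readr::write_csv(ratings, path, progress = FALSE)
  invisible(path)
}

validate_ratings <- function(ratings) {
  ratings <- tibble::as_tibble(ratings)
  if (!"segment_id" %in% names(ratings)) {
    stop("ratings data is missing required column: segment_id", call. = FALSE)
  }
  rater_cols <- setdiff(names(ratings), "segment_id")
  if (length(rater_cols) < 2) {
    stop("ratings require at least 2 rater columns", call. = FALSE)
  }
  if (nrow(ratings) < 2) {
    stop("ratings require at least 2 segments", call. = FALSE)
  }
  ratings$segment_id <- as.character(ratings$segment_id)
  if (anyDuplicated(ratings$segment_id)) {
    stop("duplicate segment_id in ratings", call. = FALSE)
  }
  m <- as.matrix(ratings[rater_cols])
  if (anyNA(m)) stop("ratings contain missing cells", call. = FALSE)
  if (!all(m %in% c(0, 1))) {
    stop("ratings must be binary: 0 (non-smile) or 1 (smile)", call. = FALSE)
  }
  for (nm in rater_cols) ratings[[nm]] <- as.integer(ratings[[nm]])
  ratings
}

rating_matrix <- function(ratings) {
  ratings <- validate_ratings(ratings)
  m <- as.matrix(ratings[setdiff(names(ratings), "segment_id")])
  rownames(m) <- ratings$segment_id
  m
}

#' Fleiss' kappa for a binary multi-rater panel
#'
#' Chance-corrected agreement for `r` raters judging `n` items. With
#' `n_ij` the number of raters assigning item `i` to category `j`,
#' per-item agreement is `P_i = (sum_j n_ij^2 - r) / (r (r - 1))`,
#' the mean observed agreement is `Pbar = mean(P_i)`, and chance agreement
#' is `Pe = sum_j p_j^2` with `p_j` the overall share of ratings in
#' category `j`; `kappa = (Pbar - Pe) / (1 - Pe)`.
#'
#' The standard error is the Fleiss-Nee-Landis large-sample standard error
#' of overall kappa, which for binary ratings reduces to
#' `sqrt(2 / (n r (r - 1)))`. The 95% confidence interval is the Wald
#' interval `kappa +/- 1.96 SE`, deliberately not truncated at 1, and the
#' p-value is a one-sided z-test of kappa = 0 against kappa > 0.
#'
#' @param ratings A ratings tibble (see [read_ratings()]) or an
#'   `n x r` binary matrix.
#' @return An object of class `agreement`: a list with `method`, `kappa`,
#'   `se`, `ci` (length-2), `p_value`, `z`, `n_items`, `n_raters`,
#'   `p_bar` (observed agreement) and `p_e` (chance agreement).
#' @references Fleiss JL, Nee JCM, Landis JR (1979). Large sample variance
#'   of kappa in the case of different sets of raters. Psychological
#'   Bulletin 86(5), 974-977.
#' @export
fleiss_kappa <- function(ratings) {
  m <- if (is.matrix(ratings)) ratings else rating_matrix(ratings)
  n <- nrow(m)
  r <- ncol(m)
  if (n < 2 || r < 2) stop("need at least 2 items and 2 raters", call. = FALSE)
  n1 <- rowSums(m)
  n0 <- r - n1
  p_i <- (n1^2 + n0^2 - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p1 <- sum(n1) / (n * r)
  p_j <- c(1 - p1, p1)
  p_e <- sum(p_j^2)
  if (p_e >= 1) {
    stop("Fleiss' kappa undefined: all ratings fall in a single category",
         call. = FALSE)
  }
  kappa <- (p_bar - p_e) / (1 - p_e)
  q_j <- 1 - p_j
  spq <- sum(p_j * q_j)
  se <- sqrt(2) * sqrt(spq^2 - sum(p_j * q_j * (q_j - p_j))) /
    (spq * sqrt(n * r * (r - 1)))
  z <- kappa / se
  structure(
    list(
      method = "Fleiss' kappa",
      kappa = kappa, se = se,
      ci = kappa + c(-1, 1) * qnorm(0.975) * se,
      p_value = pnorm(z, lower.tail = FALSE), z = z,
      n_items = n, n_raters = r, p_bar = p_bar, p_e = p_e
    ),
    class = "agreement"
  )
}

#' Consensus labels by majority vote
#'
#' Each item receives the label chosen by more than half of the raters.
#' With an odd panel a tie is impossible; with an even panel a tie raises
#' an error unless a tie policy is supplied.
#'
#' @param ratings A ratings tibble or binary matrix (see [fleiss_kappa()]).
#' @param tie Tie policy for even panels: `"error"` (default), `"zero"` or
#'   `"one"`.
#' @return A tibble `segment_id`, `label` of consensus labels.
#' @export
majority_vote <- function(ratings, tie = c("error", "zero", "one")) {
  tie <- match.arg(tie)
  m <- if (is.matrix(ratings)) ratings else rating_matrix(ratings)
  r <- ncol(m)
  ones <- rowSums(m)
  label <- ifelse(ones > r / 2, 1L, 0L)
  tied <- ones * 2 == r
  if (any(tied)) {
    if (tie == "error") {
      stop("majority tie for segment(s): ",
           paste(utils::head(rownames(m)[tied], 5), collapse = ", "),
           "; supply a tie policy", call. = FALSE)
    }
    label[tied] <- if (tie == "one") 1L else 0L
  }
  tibble::tibble(
    segment_id = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
                 else rownames(m),
    label = as.integer(label)
  )
}

#' Count non-unanimous items in a rater panel
#'
#' @param ratings A ratings tibble or binary matrix.
#' @return Integer: the number of items on which the raters disagree.
#' @export
disagreement_count <- function(ratings) {
  m <- if (is.matrix(ratings)) ratings else rating_matrix(ratings)
  sum(rowSums(m) %% ncol(m) != 0)
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("%s: %.4f (95%% CI [%.4f, %.4f]; p %s)\n",
              x$method, x$kappa, x$ci[1], x$ci[2], format_p(x$p_value)))
  cat(sprintf("  observed agreement %.4f, chance agreement %.4f; n = %d\n",
              x$p_bar, x$p_e, x$n_items))
  invisible(x)
}

format_p <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("= %.3f", p)
}
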