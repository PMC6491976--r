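#' Construct a multiarm stepped-wedge trial design
#'
#' A design bundles the allocation matrix `X` with the per-cluster-period
#' sample size `m` and the number of intervention arms `D`. Row `i` of `X`
#' gives the sequence of arms (integers `0` to `D - 1`) received by cluster
#' `i` across the `T` time periods.
#'
#' In the nested-intervention setting each arm `d` extends arm `d - 1`, and a
#' cluster may never step "down": rows of `X` must be nondecreasing. This is
#' checked by default; pass `monotone = FALSE` for crossover-style designs
#' where arms may be revisited.
#'
#' An arm that appears in no cell of `X` has an inestimable effect; the
#' constructor warns (rather than errors) so that such degenerate designs can
#' still be inspected with [check_identifiability()].
#'
#' @param X integer matrix (`C` rows, `T` columns) of arm labels in
#'   `0:(D - 1)`, or a digit string as accepted by [parse_design()].
#' @param m positive integer, measurements per cluster per period.
#' @param D integer `>= 2`, number of arms. Defaults to `max(X) + 1`.
#' @param monotone logical; enforce nondecreasing rows (default `TRUE`).
#' @param C,T dimensions of `X`, required only when `X` is a digit string.
#' @return An object of class `masw_design` with elements `X`, `m`, `C`, `T`,
#'   `D`.
#' @examples
#' d <- masw_design("0011", m = 5, C = 2, T = 2)
#' d$D
#' @seealso [parse_design()], [design_string()], [check_identifiability()]
#' @export
masw_design <- function(X, m, D = NULL, monotone = TRUE, C = NULL, T = NULL) {
  if (is.character(X)) {
    X <- parse_design(X, C = C, T = T)
  }
  if (!is.matrix(X)) stop("X must be a matrix (or digit string)")
  storage.mode(X) <- "integer"
  if (any(is.na(X))) stop("X contains non-integer entries")
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("m must be a positive integer")
  }
  if (is.null(D)) D <- max(X) + 1L
  D <- as.integer(D)
  if (D < 2L) stop("D must be at least 2")
  if (any(X < 0L | X >= D)) stop("entries of X must lie in 0:(D-1)")
  if (monotone && ncol(X) > 1L) {
    diffs <- X[, -1L, drop = FALSE] - X[, -ncol(X), drop = FALSE]
    if (any(diffs < 0L)) {
      stop("rows of X must be nondecreasing (X[i,j] >= X[i,j-1]); ",
           "use monotone = FALSE for crossover designs")
    }
  }
  missing_arms <- setdiff(0:(D - 1L), unique(as.vector(X)))
  if (length(missing_arms)) {
    warning("arm(s) ", paste(missing_arms, collapse = ", "),
            " never allocated: their effects are inestimable")
  }
  structure(
    list(X = X, m = as.integer(m), C = nrow(X), T = ncol(X), D = D),
    class = "masw_design"
  )
}

#' @export
print.masw_design <- function(x, ...) {
  cat(sprintf(
    "Multiarm stepped-wedge design: C = %d clusters, T = %d periods, m = %d, D = %d arms\n",
    x$C, x$T, x$m, x$D
  ))
  cat(sprintf("Cost (observations m*C*T): %d\n", x$m * x$C * x$T))
  Xp <- x$X
  dimnames(Xp) <- list(paste0("cluster", seq_len(x$C)),
                       paste0("t", seq_len(x$T)))
  print(Xp)
  invisible(x)
}

#' Parse an allocation matrix from its digit-string form
#'
#' Allocation matrices are conventionally printed as the row-major
#' concatenation of their entries (e.g. `"000112000112..."`). This codec
#' reverses that: the first `T` digits form row 1, and so on.
#'
#' @param string digit string of length `C * T`.
#' @param C,T number of clusters and periods.
#' @return `C` by `T` integer matrix.
#' @examples
#' parse_design("0011", C = 2, T = 2)
#' @export
parse_design <- function(string, C, T) {
  string <- gsub("[[:space:]]", "", string)
  if (is.null(C) || is.null(T)) stop("C and T are required to parse a design string")
  digits <- strsplit(string, "")[[1L]]
  if (length(digits) != C * T) {
    stop(sprintf("design string has %d digits; expected C*T = %d",
                 length(digits), C * T))
  }
  if (!all(grepl("^[0-9]$", digits))) stop("design string must contain digits only")
  matrix(as.integer(digits), nrow = C, ncol = T, byrow = TRUE)
}

#' Format a design (or allocation matrix) as a digit string
#'
#' Inverse of [parse_design()]; round-trips exactly.
#'
#' @param design a `masw_design` or an integer matrix.
#' @return single string, the row-major concatenation of the entries.
#' @export
design_string <- function(design) {
  X <- if (inherits(design, "masw_design")) design$X else design
  paste(apply(X, 1L, paste, collapse = ""), collapse = "")
}

#' Read a design from a text file
#'
#' Accepts either a single-line digit string (requires `C` and `T`) or a CSV
#' of integers with one row per cluster.
#'
#' @param file path.
#' @param m measurements per cluster-period.
#' @param D number of arms (default inferred).
#' @param C,T dimensions, needed for the digit-string format.
#' @param ... passed to [masw_design()].
#' @return a `masw_design`.
#' @export
read_design <- function(file, m, D = NULL, C = NULL, T = NULL, ...) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 1L && !grepl(",", lines)) {
    return(masw_design(trimws(lines), m = m, D = D, C = C, T = T, ...))
  }
  X <- as.matrix(read.csv(file, header = FALSE))
  dimnames(X) <- NULL
  masw_design(X, m = m, D = D, ...)
}

#' Write a design to a text file
#'
#' @param design a `masw_design`.
#' @param file path.
#' @param format `"string"` (single-line digit string) or `"csv"`.
#' @return `file`, invisibly.
#' @export
write_design <- function(design, file, format = c("string", "csv")) {
  format <- match.arg(format)
  if (format == "string") {
    writeLines(design_string(design), file)
  } else {
    write.table(design$X, file, sep = ",", row.names = FALSE,
                col.names = FALSE)
  }
  invisible(file)
}

#' Check identifiability of the fixed effects under a design
#'
#' The linear mixed model has `p = T + D - 1` fixed effects (intercept,
#' `T - 1` period effects and `D - 1` intervention effects). They are jointly
#' estimable exactly when the stacked fixed-effect design matrix has full
#' column rank, which depends only on the set of distinct treatment sequences
#' in `X` (not on `m` or on row multiplicities).
#'
#' @param design a `masw_design`.
#' @return `TRUE` if all fixed effects are estimable, else `FALSE`.
#' @examples
#' # intervention indicator collinear with the period-2 effect:
#' d <- masw_design(matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE), m = 1)
#' check_identifiability(d)
#' @export
check_identifiability <- function(design) {
  stopifnot(inherits(design, "masw_design"))
  seqs <- unique(design$X)
  A <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
    sequence_fixed_matrix(seqs[i, ], design$T, design$D)
  }))
  qr(A)$rank == ncol(A)
}

# Fixed-effect matrix for a single cluster-sequence at m = 1:
# columns [intercept | period 2..T dummies | I{x >= 1} .. I{x >= D-1}].
sequence_fixed_matrix <- function(s, T, D) {
  p <- T + D - 1L
  A <- matrix(0, T, p)
  A[, 1L] <- 1
  if (T > 1L) for (j in 2:T) A[j, j] <- 1
  for (d in seq_len(D - 1L)) A[, T + d] <- as.numeric(s >= d)
  colnames(A) <- fixed_effect_names(T, D)
  A
}

fixed_effect_names <- function(T, D) {
  c("(Intercept)",
    if (T > 1L) paste0("period", 2:T),
    paste0("arm", seq_len(D - 1L)))
}

intervention_coords <- function(T, D) {
  T + seq_len(D - 1L)
}
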