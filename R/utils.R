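#' @keywords internal
"_PACKAGE"

# Fixed label order used everywhere: index 0 = negative class, then the five
# evaluated CPR classes in ascending numeric order.
CPI_CLASS_ORDER <- c("NEG", "CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")
EVALUATED_CPR <- c("CPR:3", "CPR:4", "CPR:5", "CPR:6", "CPR:9")
ALL_CPR <- paste0("CPR:", 1:10)

#' Fixed class order of the six-way CPI label set
#'
#' The negative class first, then the five evaluated ChemProt relation
#' classes (CPR:3 upregulator/activator, CPR:4 downregulator/inhibitor,
#' CPR:5 agonist, CPR:6 antagonist, CPR:9 substrate/product-of) in numeric
#' order. Label ids are 0-based positions in this vector.
#'
#' @return Character vector of length 6.
#' @export
cpi_classes <- function() CPI_CLASS_ORDER

#' Map a class label to its 0-based id and back
#'
#' @param label character vector of labels from [cpi_classes()].
#' @return `class_to_id`: integer vector of 0-based ids. `id_to_class`:
#'   character vector of labels.
#' @export
class_to_id <- function(label) {
  idx <- match(label, CPI_CLASS_ORDER)
  if (anyNA(idx)) {
    stop("unknown class label(s): ", paste(unique(label[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' @rdname class_to_id
#' @param id integer vector of 0-based label ids.
#' @export
id_to_class <- function(id) {
  if (any(id < 0L | id > 5L)) stop("label id out of range [0, 6)")
  CPI_CLASS_ORDER[id + 1L]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax of a matrix (or a plain vector).
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 1L, max)
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

# log-softmax of a vector, numerically stable.
log_softmax <- function(x) {
  m <- max(x)
  x - m - log(sum(exp(x - m)))
}

# Deterministic uniform/gaussian init. Glorot-style scale for weight
# matrices, zeros for biases.
init_matrix <- function(nrow, ncol) {
  s <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -s, s), nrow, ncol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop(name, " must be a single non-negative number")
  }
}
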