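#' The nine logic tasks
#'
#' Digital organisms are rewarded for performing one- and two-input logic
#' operations. The canonical ladder of nine tasks, in order of increasing
#' computational complexity, is NOT, NAND, AND, ORN, OR, ANDN, NOR, XOR, EQU.
#' A genotype is fully described by which of these tasks it can perform.
#'
#' @return Character vector of the nine task names, in canonical order.
#' @export
task_names <- function() {
  c("NOT", "NAND", "AND", "ORN", "OR", "ANDN", "NOR", "XOR", "EQU")
}

#' Per-task complexity weights
#'
#' Complexity follows the standard reward ladder: the two one-instruction
#' tasks weigh 1, up to EQU which weighs 5. Merit rewards are multiplicative
#' in `2^complexity`, so a genotype doing more complex tasks earns a larger
#' share of the CPU when the matching resources are available.
#'
#' @return Named integer vector of length 9.
#' @export
task_complexity <- function() {
  stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L), task_names())
}

# Bit weights for packing a 9-element task profile into one integer (0..511).
.task_bit <- 2L^(0:8)

#' Pack a task profile into an integer mask
#'
#' Task sets are stored as 9-bit integer masks (0--511) so that infection
#' compatibility reduces to a bitwise AND. Accepts a character vector of task
#' names, a logical vector of length 9, or an already-packed mask.
#'
#' @param tasks Character vector of task names (subset of [task_names()]),
#'   logical vector of length 9, or a single integer in `[0, 511]`.
#' @return Integer scalar in `[0, 511]`.
#' @export
#' @examples
#' task_mask(c("NOT", "AND"))
#' task_mask(character(0)) # the empty task set
task_mask <- function(tasks) {
  if (is.numeric(tasks) && length(tasks) == 1L) {
    m <- as.integer(tasks)
    if (is.na(m) || m < 0L || m > 511L) stop("task mask must be in [0, 511]")
    return(m)
  }
  if (is.logical(tasks)) {
    if (length(tasks) != 9L) stop("logical task profile must have length 9")
    return(as.integer(sum(.task_bit[tasks])))
  }
  if (is.character(tasks)) {
    idx <- match(tasks, task_names())
    if (anyNA(idx)) stop("unknown task name: ", paste(tasks[is.na(idx)], collapse = ", "))
    return(as.integer(sum(.task_bit[unique(idx)])))
  }
  stop("cannot interpret task profile")
}

#' Unpack a task mask
#'
#' @param mask Integer mask(s) in `[0, 511]`.
#' @return For a single mask, a logical vector of length 9 named by task;
#'   for a vector of masks, a logical matrix with one row per mask.
#' @export
mask_tasks <- function(mask) {
  mask <- as.integer(mask)
  if (any(mask < 0L | mask > 511L, na.rm = TRUE)) stop("task mask must be in [0, 511]")
  m <- outer(mask, .task_bit, function(x, b) bitwAnd(x, b) > 0L)
  colnames(m) <- task_names()
  if (length(mask) == 1L) m[1L, ] else m
}

#' Number of tasks in a mask
#' @param mask Integer mask(s).
#' @return Integer count(s) of set task bits.
#' @export
task_count <- function(mask) {
  n <- integer(length(mask))
  for (b in .task_bit) n <- n + (bitwAnd(as.integer(mask), b) > 0L)
  n
}

#' Summed and maximum task complexity of a mask
#' @param mask Integer mask(s).
#' @return For `task_complexity_sum`, numeric summed complexity weights;
#'   for `task_complexity_max`, the maximum weight (0 for the empty set).
#' @export
task_complexity_sum <- function(mask) {
  cx <- task_complexity()
  s <- numeric(length(mask))
  for (t in 1:9) s <- s + cx[t] * (bitwAnd(as.integer(mask), .task_bit[t]) > 0L)
  unname(s)
}

#' @rdname task_complexity_sum
#' @export
task_complexity_max <- function(mask) {
  cx <- task_complexity()
  m <- numeric(length(mask))
  for (t in 1:9) m <- pmax(m, cx[t] * (bitwAnd(as.integer(mask), .task_bit[t]) > 0L))
  unname(m)
}

#' Infection compatibility
#'
#' A pathogen can infect a host if and only if it can perform at least one of
#' the logic tasks the host performs: infection requires a non-empty task
#' intersection. A pathogen with no tasks can infect nothing, and a host with
#' no tasks is universally resistant.
#'
#' @param pathogen,host Task profiles (anything [task_mask()] accepts), or
#'   equal-length integer mask vectors for vectorised use.
#' @return Logical: `TRUE` where the task intersection is non-empty.
#' @export
#' @examples
#' can_infect(c("AND"), c("NOT", "AND")) # TRUE
#' can_infect(character(0), c("NOT"))    # FALSE
can_infect <- function(pathogen, host) {
  p <- if (is.numeric(pathogen) && length(pathogen) > 1L) as.integer(pathogen) else task_mask(pathogen)
  h <- if (is.numeric(host) && length(host) > 1L) as.integer(host) else task_mask(host)
  bitwAnd(p, h) > 0L
}
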