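#' Construct a probabilistic inference task
#'
#' A task presents two options (A, B) described by four binary cues whose
#' predictions ("+" = +1, "-" = -1) have explicit validities. Validity is the
#' proportion of correct past predictions, so chance level is .50 for a
#' binary choice and informative validities lie strictly inside (0.5, 1).
#'
#' Cues are stored in descending validity order (ties keep input order); if
#' the supplied validities are not sorted, cue rows are permuted accordingly.
#'
#' @param validities numeric vector of 4 cue validities, each in (0.5, 1).
#' @param cue_matrix 4 x 2 matrix of cue values in \{+1, -1\}; rows are cues,
#'   columns are options A and B.
#' @param id optional task identifier (character); autogenerated if missing.
#' @return An object of class \code{pcs_task}: a list with elements
#'   \code{id}, \code{validities}, \code{cue_matrix} and \code{dominated}
#'   (TRUE when one option is at least as good on every cue and strictly
#'   better on at least one).
#' @examples
#' t1 <- make_task(c(.87, .87, .76, .60),
#'                 matrix(c(1, 1, -1, -1, 1, -1, 1, 1), 4, 2))
#' t1$dominated
#' @export
make_task <- function(validities, cue_matrix, id = NULL) {
  validities <- as.numeric(validities)
  if (length(validities) != 4L)
    stop("exactly 4 cue validities are required")
  if (any(!is.finite(validities)) || any(validities <= 0.5) || any(validities >= 1))
    stop("validities must lie strictly within (0.5, 1)")
  cue_matrix <- as.matrix(cue_matrix)
  if (!all(dim(cue_matrix) == c(4L, 2L)))
    stop("cue_matrix must be 4 x 2")
  storage.mode(cue_matrix) <- "double"
  if (!all(cue_matrix %in% c(-1, 1)))
    stop("cue values must be +1 or -1")
  if (all(cue_matrix[, 1] == cue_matrix[, 2]))
    stop("the two option columns must not be identical")
  ord <- order(validities, decreasing = TRUE)  # stable: ties keep input order
  validities <- validities[ord]
  cue_matrix <- cue_matrix[ord, , drop = FALSE]
  dimnames(cue_matrix) <- list(paste0("cue", 1:4), c("A", "B"))
  structure(
    list(id = if (is.null(id)) paste0("task_", task_signature(validities, cue_matrix)) else as.character(id),
         validities = validities,
         cue_matrix = cue_matrix,
         dominated = is_dominated(cue_matrix)),
    class = "pcs_task")
}

# one column >= the other on every cue with at least one strict inequality
is_dominated <- function(cue_matrix) {
  d <- cue_matrix[, 1] - cue_matrix[, 2]
  (all(d >= 0) || all(d <= 0)) && any(d != 0)
}

task_signature <- function(validities, cue_matrix) {
  paste(c(sprintf("%.2f", validities), cue_matrix), collapse = "_")
}

#' @export
print.pcs_task <- function(x, ...) {
  cat("Probabilistic inference task", x$id,
      if (x$dominated) "(dominated)" else "", "\n")
  m <- cbind(v = x$validities, x$cue_matrix)
  print(m)
  invisible(x)
}

#' Swap the two options of a task
#'
#' Returns the task with columns A and B exchanged. Useful for symmetry
#' checks: any sensible strategy must swap its predicted choice and keep
#' confidence and time predictions unchanged under this relabeling.
#'
#' @param task a \code{pcs_task}.
#' @return the mirrored \code{pcs_task} (same id with suffix "_m").
#' @export
mirror_task <- function(task) {
  stopifnot(inherits(task, "pcs_task"))
  m <- task$cue_matrix[, c(2L, 1L), drop = FALSE]
  id <- if (endsWith(task$id, "_m")) sub("_m$", "", task$id) else paste0(task$id, "_m")
  make_task(task$validities, m, id = id)
}

#' Bundle tasks into a task set
#'
#' @param tasks list of \code{pcs_task} objects.
#' @return object of class \code{task_set} (a list of tasks). Duplicate
#'   (validities, cue matrix) pairs are rejected.
#' @export
task_set <- function(tasks) {
  stopifnot(all(vapply(tasks, inherits, logical(1), "pcs_task")))
  sigs <- vapply(tasks, function(t) task_signature(t$validities, t$cue_matrix), "")
  if (anyDuplicated(sigs))
    stop("duplicate tasks in task set")
  structure(tasks, class = "task_set")
}

#' @export
print.task_set <- function(x, ...) {
  cat("Task set with", length(x), "probabilistic inference tasks\n")
  invisible(x)
}

#' @export
as.data.frame.task_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(t) {
    data.frame(id = t$id,
               v1 = t$validities[1], v2 = t$validities[2],
               v3 = t$validities[3], v4 = t$validities[4],
               a1 = t$cue_matrix[1, 1], a2 = t$cue_matrix[2, 1],
               a3 = t$cue_matrix[3, 1], a4 = t$cue_matrix[4, 1],
               b1 = t$cue_matrix[1, 2], b2 = t$cue_matrix[2, 2],
               b3 = t$cue_matrix[3, 2], b4 = t$cue_matrix[4, 2])
  }))
}

#' Read / write task sets as CSV
#'
#' One row per task with columns id, v1..v4, a1..a4, b1..b4. Round-trips
#' losslessly through \code{write_tasks} then \code{read_tasks}.
#'
#' @param path file path.
#' @return \code{read_tasks} returns a \code{task_set}.
#' @export
read_tasks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("id", paste0("v", 1:4), paste0("a", 1:4), paste0("b", 1:4))
  if (!identical(names(df), expected))
    stop("task file must have columns: ", paste(expected, collapse = ", "))
  if (nrow(df) == 0L) return(task_set(list()))
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("malformed task row(s): ", paste(bad, collapse = ", "))
  task_set(lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    make_task(as.numeric(r[paste0("v", 1:4)]),
              matrix(as.numeric(c(r[paste0("a", 1:4)], r[paste0("b", 1:4)])), 4, 2),
              id = r$id)
  }))
}

#' @rdname read_tasks
#' @param tasks a \code{task_set}.
#' @export
write_tasks <- function(tasks, path) {
  stopifnot(inherits(tasks, "task_set"))
  if (length(tasks) == 0L) {
    utils::write.csv(
      data.frame(id = character(), v1 = double(), v2 = double(), v3 = double(),
                 v4 = double(), a1 = double(), a2 = double(), a3 = double(),
                 a4 = double(), b1 = double(), b2 = double(), b3 = double(),
                 b4 = double()),
      path, row.names = FALSE)
    return(invisible(path))
  }
  utils::write.csv(as.data.frame(tasks), path, row.names = FALSE)
  invisible(path)
}

#' The three example tasks printed with the stock-market paradigm
#'
#' Three canonical 4-cue, 2-option tasks used throughout the documentation
#' and tests as worked examples. Option A is, in all three, the option with
#' the higher naive-Bayes posterior.
#'
#' @return a \code{task_set} of 3 tasks with ids "task1", "task2", "task3".
#' @export
example_tasks <- function() {
  task_set(list(
    make_task(c(.87, .87, .76, .60),
              matrix(c(1, 1, -1, -1,  1, -1, 1, 1), 4, 2), id = "task1"),
    make_task(c(.94, .79, .73, .63),
              matrix(c(1, -1, 1, 1,  1, 1, -1, -1), 4, 2), id = "task2"),
    make_task(c(.77, .74, .68, .63),
              matrix(c(1, 1, -1, 1,  1, -1, 1, 1), 4, 2), id = "task3")))
}
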