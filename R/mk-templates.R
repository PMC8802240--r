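#' Build a constrained Mk rate-matrix template
#'
#' A template fixes which transitions are allowed and which free parameters
#' they share. State 0 is the "lost" (hypodermic-like) end of the scale and
#' the highest state the reciprocal-like end; Dollo-type templates forbid all
#' gains out of state 0.
#'
#' Binary (2-state) templates: `ER` (one rate both directions), `SYM`
#' (identical to ER), `ARD` (two rates), `Dollo` (only 1->0 free, 0->1
#' forbidden). Trinary (3-state): `ER` (1), `SYM` (3), `ARD` (6), `ORD`
#' (ordered, 4: 0<->1 and 1<->2 free, direct 0<->2 forbidden), `ORD-Dollo`
#' (3: 1->0, 1->2, 2->1 free; all transitions out of 0 and 2->0 forbidden)
#' and `Dollo` (4: 1->0, 1->2, 2->1, 2->0 free; 0->1 and 0->2 forbidden —
#' note the direct 2->0 loss is allowed).
#'
#' @param model Template name: `"ER"`, `"SYM"`, `"ARD"`, `"Dollo"`, `"ORD"`
#'   or `"ORD-Dollo"`.
#' @param n_states 2 or 3.
#' @return An `mk_template`: list with `name`, `n_states`, `index` (k x k
#'   integer matrix; 0 = forbidden/diagonal, p = id of the shared free
#'   parameter) and `n_par`.
#' @examples
#' build_template("Dollo", 2)$n_par      # 1
#' build_template("ORD-Dollo", 3)$n_par  # 3
#' @export
build_template <- function(model, n_states) {
  stopifnot(n_states %in% c(2L, 3L))
  model <- match.arg(model, c("ER", "SYM", "ARD", "Dollo", "ORD", "ORD-Dollo"))
  k <- as.integer(n_states)
  idx <- matrix(0L, k, k)
  set <- function(from, to, p) idx[from + 1L, to + 1L] <<- as.integer(p)
  if (k == 2L) {
    switch(model,
      "ER" = , "SYM" = { set(0, 1, 1); set(1, 0, 1) },
      "ARD" = { set(0, 1, 1); set(1, 0, 2) },
      "Dollo" = { set(1, 0, 1) },
      stop("model '", model, "' requires 3 states")
    )
  } else {
    switch(model,
      "ER" = { for (i in 0:2) for (j in 0:2) if (i != j) set(i, j, 1) },
      "SYM" = { set(0, 1, 1); set(1, 0, 1); set(0, 2, 2); set(2, 0, 2)
                set(1, 2, 3); set(2, 1, 3) },
      "ARD" = { p <- 0L
                for (i in 0:2) for (j in 0:2) if (i != j) {
                  p <- p + 1L; set(i, j, p) } },
      "ORD" = { set(0, 1, 1); set(1, 0, 2); set(1, 2, 3); set(2, 1, 4) },
      "ORD-Dollo" = { set(1, 0, 1); set(1, 2, 2); set(2, 1, 3) },
      "Dollo" = { set(1, 0, 1); set(1, 2, 2); set(2, 1, 3); set(2, 0, 4) }
    )
  }
  structure(list(name = model, n_states = k, index = idx,
                 n_par = max(idx)),
            class = "mk_template")
}

#' @export
print.mk_template <- function(x, ...) {
  cat("Mk template", x$name, "on", x$n_states, "states,", x$n_par,
      "free parameter(s)\n")
  print(x$index)
  invisible(x)
}

#' Human-readable labels for a template's free parameters
#'
#' @param template An `mk_template`.
#' @return Character vector of length `n_par`, e.g. `"1->0"` or
#'   `"0->1=1->0"` for shared parameters.
#' @export
template_par_labels <- function(template) {
  k <- template$n_states
  vapply(seq_len(template$n_par), function(p) {
    cells <- which(template$index == p, arr.ind = TRUE)
    paste(sprintf("%d->%d", cells[, 1L] - 1L, cells[, 2L] - 1L),
          collapse = "=")
  }, character(1L))
}

#' Assemble the rate matrix Q from a template and rate values
#'
#' Forbidden cells stay exactly zero at all parameter values; the diagonal is
#' the negative row sum.
#'
#' @param template An `mk_template`.
#' @param rates Non-negative numeric vector, one entry per free parameter.
#' @return k x k rate matrix (events per unit branch length).
#' @export
mk_Q <- function(template, rates) {
  if (length(rates) != template$n_par) {
    stop("expected ", template$n_par, " rate(s), got ", length(rates))
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and non-negative")
  }
  k <- template$n_states
  Q <- matrix(0, k, k)
  free <- template$index > 0L
  Q[free] <- rates[template$index[free]]
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(as.character(0:(k - 1L)), as.character(0:(k - 1L)))
  Q
}
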