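#' Exclusion ledger
#'
#' An ordered record of filtering stages: each entry names the filter,
#' the number of items removed and the number remaining, kept separately
#' for variants and samples.  Remaining counts are strictly
#' non-increasing and conserve the input count (input = remaining + sum
#' removed).
#'
#' @param n_initial Item count before any filtering.
#' @param scope `"sample"` or `"variant"`.
#' @param label Free-text description of the item set.
#' @return An `exclusion_ledger` object.
#' @export
new_ledger <- function(n_initial, scope = c("sample", "variant"),
                       label = scope) {
  scope <- match.arg(scope)
  if (n_initial < 0) stop_invalid("n_initial must be non-negative")
  structure(list(scope = scope, label = label,
                 n_initial = as.integer(n_initial),
                 entries = data.frame(filter = character(),
                                      removed = integer(),
                                      remaining = integer(),
                                      note = character(),
                                      stringsAsFactors = FALSE)),
            class = "exclusion_ledger")
}

#' @rdname new_ledger
#' @param ledger An `exclusion_ledger`.
#' @param filter Name of the filtering stage.
#' @param removed Items removed at this stage.
#' @param note Optional free-text note (e.g. a skipped-stage warning).
#' @export
ledger_add <- function(ledger, filter, removed, note = "") {
  removed <- as.integer(removed)
  prev <- ledger_remaining(ledger)
  if (removed < 0L || removed > prev)
    stop_invalid("removed count ", removed, " outside [0, ", prev,
                 "] at stage '", filter, "'")
  ledger$entries <- rbind(ledger$entries,
                          data.frame(filter = filter, removed = removed,
                                     remaining = prev - removed, note = note,
                                     stringsAsFactors = FALSE))
  ledger
}

#' @rdname new_ledger
#' @export
ledger_remaining <- function(ledger) {
  if (nrow(ledger$entries) == 0L) ledger$n_initial
  else ledger$entries$remaining[nrow(ledger$entries)]
}

#' @rdname new_ledger
#' @description `ledger_replay()` runs a named vector of removal counts
#' through a fresh ledger, returning the ledger; useful for auditing
#' published filtering narratives from their printed counts alone.
#' @param removals Named integer vector of per-stage removal counts.
#' @export
ledger_replay <- function(n_initial, removals,
                          scope = c("sample", "variant")) {
  led <- new_ledger(n_initial, match.arg(scope))
  for (nm in names(removals)) led <- ledger_add(led, nm, removals[[nm]])
  led
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion ledger (%s: %s), initial n = %d\n",
              x$scope, x$label, x$n_initial))
  if (nrow(x$entries)) {
    for (i in seq_len(nrow(x$entries))) {
      e <- x$entries[i, ]
      cat(sprintf("  %-28s -%7d  => %8d%s\n", e$filter, e$removed,
                  e$remaining, if (nzchar(e$note)) paste0("  [", e$note, "]")
                  else ""))
    }
  } else cat("  (no stages recorded)\n")
  invisible(x)
}

# Conservation check: input = final remaining + sum(removed).
ledger_conserved <- function(ledger) {
  ledger$n_initial ==
    ledger_remaining(ledger) + sum(ledger$entries$removed)
}

#' Serialize ledgers to JSON
#'
#' @param ledgers A named list of `exclusion_ledger` objects.
#' @param path Output path.
#' @export
write_ledger_json <- function(ledgers, path) {
  out <- lapply(ledgers, function(l)
    list(scope = l$scope, label = l$label, n_initial = l$n_initial,
         entries = l$entries))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
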