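#' Write a game trace as delimited text
#'
#' Writes three files under `dir`: `strategies.tsv` (labels, nodes in
#' rows), `payoffs.tsv` (floats) and `meta.json` (game parameters).
#'
#' @param trace A `game_trace`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_game_trace <- function(trace, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(strategy_matrix(trace), file.path(dir, "strategies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(trace$payoffs, file.path(dir, "payoffs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  tab <- trace$table
  meta <- list(strategies = rownames(tab), b = attr(tab, "b"),
               c = attr(tab, "c"), chi = attr(tab, "chi"),
               a = trace$a, reshuffle_period = trace$reshuffle_period,
               seed = trace$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a game trace written by [write_game_trace()]
#'
#' @param dir Directory holding `strategies.tsv`, `payoffs.tsv`,
#'   `meta.json`.
#' @return A `game_trace` (without the generating network).
#' @export
read_game_trace <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  tab <- payoff_table(meta$strategies, b = meta$b, c = meta$c,
                      chi = if (is.null(meta$chi)) 2 else meta$chi)
  S_lab <- as.matrix(read.table(file.path(dir, "strategies.tsv"),
                                sep = "\t", colClasses = "character"))
  Y <- as.matrix(read.table(file.path(dir, "payoffs.tsv"), sep = "\t"))
  S <- matrix(match(S_lab, rownames(tab)), nrow(S_lab), ncol(S_lab))
  if (anyNA(S)) stop("strategy label not present in the payoff table")
  structure(list(strategies = S, strategy_levels = rownames(tab),
                 payoffs = unname(Y), table = tab, a = meta$a,
                 reshuffle_period = meta$reshuffle_period,
                 seed = meta$seed, network = NULL),
            class = "game_trace")
}
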