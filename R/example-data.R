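# Worked-example fixtures: the published two-factor social-anxiety
# illustration that the scoring algebra is demonstrated on. These are
# printed values (3-decimal precision), used in documentation, tests and
# the acceptance script as desk-scale inputs.

#' Worked-example item texts
#'
#' The ten social-anxiety items of the worked clinical example, each
#' prefixed in administration by "Since the last assessment, I have...".
#'
#' @return Named character vector (`item1`..`item10`).
#' @export
example_item_texts <- function() {
  c(item1 = "Felt moments of sudden terror, fear, or fright in social situations.",
    item2 = "Felt anxious, worried, or nervous about social situations.",
    item3 = "Had thoughts of being rejected, humiliated, embarrassed, ridiculed or offending others.",
    item4 = "Felt a racing heart, sweaty, trouble breathing, faint, or shaky in social situations.",
    item5 = "Felt tense muscles, felt on edge or restless, or had trouble relaxing in social situations.",
    item6 = "Avoided, or did not approach or enter, social situations.",
    item7 = "Left social situations early or participated only minimally (eg, said little or avoided eye contact)",
    item8 = "Spent a lot of time preparing what to say or how to act in social situations.",
    item9 = "Distracted myself to avoid thinking about social situations.",
    item10 = "Needed help to cope with social situations (eg, with alcohol, medications, or superstitious objects).")
}

#' Worked-example exploratory loading matrix
#'
#' Oblimin-rotated two-factor loadings of the worked example
#' (loadings below .10 were not reported and are stored as 0).
#'
#' @return `10 x 2` matrix with item-id rownames.
#' @export
example_efa_loadings <- function() {
  L <- rbind(
    item1  = c(0.31, 0.40),
    item2  = c(0.97, 0.00),
    item3  = c(0.00, 0.58),
    item4  = c(0.00, 0.57),
    item5  = c(0.00, 0.65),
    item6  = c(0.34, 0.40),
    item7  = c(0.00, 0.43),
    item8  = c(0.00, 0.49),
    item9  = c(0.00, 0.56),
    item10 = c(0.00, 0.00))
  colnames(L) <- c("F1", "F2")
  L
}

#' Worked-example confirmatory loading matrix
#'
#' Estimated confirmatory loadings of the worked example (zeros where the
#' pattern fixed a loading to zero; item 10 was excluded by the .30 rule).
#' Factor correlation in that model: .243.
#'
#' @return `9 x 2` matrix with item-id rownames.
#' @export
example_cfa_loadings <- function() {
  L <- rbind(
    item1 = c(0.569, 0.129),
    item2 = c(0.810, 0.000),
    item3 = c(0.000, 0.624),
    item4 = c(0.000, 0.519),
    item5 = c(0.000, 0.657),
    item6 = c(0.626, 0.094),
    item7 = c(0.000, 0.368),
    item8 = c(0.000, 0.670),
    item9 = c(0.000, 0.437))
  colnames(L) <- c("F1", "F2")
  L
}

#' Worked-example variance shares
#'
#' The within-time and between-time explained-variance percentages of the
#' worked example's two factors, as printed: within (34.27, 47.27),
#' between (22.96, 6.1).
#'
#' @return List with numeric vectors `within` and `between` (percent).
#' @export
example_variance_shares <- function() {
  list(within = c(F1 = 34.27, F2 = 47.27),
       between = c(F1 = 22.96, F2 = 6.1))
}
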