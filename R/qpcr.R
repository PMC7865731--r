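#' Relative quantification of qPCR Cq tables
#'
#' Three relative-expression methods for tidy Cq tables with columns
#' `gene`, `condition` (`"treated"` / `"untreated"`), `replicate`, `cq`.
#' Replicates are aggregated by the arithmetic mean of Cq before any
#' exponentiation. Writing `A`/`B` for the target gene's mean Cq in the
#' untreated/treated sample and `F`/`G` for the reference gene's:
#'
#' * `ddct_fold()`: the 2^-ddCt method, `fold = 2^((A - B) - (F - G))`.
#' * `pfaffl_fold()`: the efficiency-corrected method,
#'   `fold = e_target^(A - B) / e_reference^(F - G)`, with per-primer
#'   amplification efficiencies in `(1, 2]` (defaults 1.85 for the target
#'   and 1.97 for the reference primer pair).
#' * `pfaffl_min_ref_fold()`: the same efficiency model, but each
#'   reaction's quantity is expressed relative to the reaction of that gene
#'   with the lowest mean Cq, so within-gene quantities are on a common
#'   scale with maximum 1.
#'
#' @param table Tidy Cq tibble (`gene, condition, replicate, cq`).
#' @param gene Target gene name.
#' @param reference Reference (housekeeping) gene name.
#' @return A one-row tibble: `gene, method, fold, a, b, f, g` (the mean Cq
#'   inputs). `pfaffl_min_ref_fold()` additionally carries the per-reaction
#'   relative quantities as attribute `quantities`.
#' @name qpcr_fold
#' @examples
#' tab <- gen_qpcr_table("Grm2", true_fold = 0.25, reference_genes = "Gapdh",
#'                       cq_noise_sd = 0, seed = 3)
#' ddct_fold(tab, "Grm2", "Gapdh")
NULL

check_cq_table <- function(table, genes) {
  need <- c("gene", "condition", "replicate", "cq")
  if (!all(need %in% names(table))) {
    rlang::abort("Cq table needs columns gene, condition, replicate, cq.")
  }
  if (!all(is.finite(table$cq)) || any(table$cq <= 0)) {
    rlang::abort("Cq values must be finite and > 0.")
  }
  for (g in genes) {
    for (cond in c("treated", "untreated")) {
      if (!any(table$gene == g & table$condition == cond)) {
        rlang::abort(sprintf("no '%s' replicates for gene '%s'.", cond, g))
      }
    }
  }
  invisible(table)
}

mean_cq <- function(table, gene, condition) {
  mean(table$cq[table$gene == gene & table$condition == condition])
}

#' @rdname qpcr_fold
#' @export
ddct_fold <- function(table, gene, reference) {
  check_cq_table(table, c(gene, reference))
  a <- mean_cq(table, gene, "untreated")
  b <- mean_cq(table, gene, "treated")
  f <- mean_cq(table, reference, "untreated")
  g <- mean_cq(table, reference, "treated")
  tibble::tibble(gene = gene, method = "ddct",
                 fold = 2^((a - b) - (f - g)),
                 a = a, b = b, f = f, g = g)
}

#' @rdname qpcr_fold
#' @param e_target,e_reference Amplification efficiencies of the target and
#'   reference primer pairs, in `(1, 2]` (2 = perfect doubling).
#' @export
pfaffl_fold <- function(table, gene, reference,
                        e_target = 1.85, e_reference = 1.97) {
  check_cq_table(table, c(gene, reference))
  check_efficiency(e_target)
  check_efficiency(e_reference)
  a <- mean_cq(table, gene, "untreated")
  b <- mean_cq(table, gene, "treated")
  f <- mean_cq(table, reference, "untreated")
  g <- mean_cq(table, reference, "treated")
  tibble::tibble(gene = gene, method = "pfaffl",
                 fold = e_target^(a - b) / e_reference^(f - g),
                 a = a, b = b, f = f, g = g)
}

check_efficiency <- function(e) {
  if (!is.numeric(e) || length(e) != 1L || e <= 1 || e > 2) {
    rlang::abort("amplification efficiencies must lie in (1, 2].")
  }
  invisible(e)
}

#' @rdname qpcr_fold
#' @export
pfaffl_min_ref_fold <- function(table, gene, reference,
                                e_target = 1.85, e_reference = 1.97) {
  check_cq_table(table, c(gene, reference))
  check_efficiency(e_target)
  check_efficiency(e_reference)
  rel_quant <- function(g, e) {
    ms <- unname(vapply(c("untreated", "treated"), function(cond) {
      mean_cq(table, g, cond)
    }, numeric(1)))
    ref_cq <- min(ms)      # reaction with the lowest mean Cq
    tibble::tibble(gene = g, condition = c("untreated", "treated"),
                   mean_cq = ms, rel_quantity = e^(ref_cq - ms))
  }
  qt <- rel_quant(gene, e_target)
  qr <- rel_quant(reference, e_reference)
  fold <- (qt$rel_quantity[qt$condition == "treated"] /
             qt$rel_quantity[qt$condition == "untreated"]) /
    (qr$rel_quantity[qr$condition == "treated"] /
       qr$rel_quantity[qr$condition == "untreated"])
  out <- tibble::tibble(
    gene = gene, method = "pfaffl_min_ref", fold = fold,
    a = qt$mean_cq[qt$condition == "untreated"],
    b = qt$mean_cq[qt$condition == "treated"],
    f = qr$mean_cq[qr$condition == "untreated"],
    g = qr$mean_cq[qr$condition == "treated"])
  attr(out, "quantities") <- dplyr::bind_rows(qt, qr)
  out
}

#' Fold changes against each reference gene plus a combined value
#'
#' Computes the fold change of a target gene against every reference gene
#' separately and, in addition, against a synthetic combined reference
#' whose Cq is the arithmetic mean of the reference genes' Cq within each
#' condition.
#'
#' @param table Tidy Cq tibble.
#' @param gene Target gene.
#' @param reference_genes Character vector of reference genes; defaults to
#'   the table's `reference_genes` attribute.
#' @param method `"ddct"` or `"pfaffl"`.
#' @param e_target,e_reference Efficiencies for the Pfaffl method.
#' @return A tibble with one row per reference plus a `"combined"` row.
#' @export
multi_reference_summary <- function(table, gene, reference_genes = NULL,
                                    method = c("ddct", "pfaffl"),
                                    e_target = 1.85, e_reference = 1.97) {
  method <- match.arg(method)
  reference_genes <- reference_genes %||% attr(table, "reference_genes")
  if (is.null(reference_genes) || length(reference_genes) == 0) {
    rlang::abort("no reference genes supplied.")
  }
  fc <- function(tab, ref) {
    if (method == "ddct") ddct_fold(tab, gene, ref)
    else pfaffl_fold(tab, gene, ref, e_target, e_reference)
  }
  per_ref <- purrr::map_dfr(reference_genes, function(ref) {
    dplyr::mutate(fc(table, ref), reference = ref, .before = 1L)
  })
  combined_rows <- dplyr::summarise(
    dplyr::group_by(
      table[table$gene %in% reference_genes, , drop = FALSE],
      .data$condition, .data$replicate),
    gene = "..combined..", cq = mean(.data$cq), .groups = "drop")
  tab2 <- dplyr::bind_rows(
    table[table$gene == gene, c("gene", "condition", "replicate", "cq")],
    combined_rows[, c("gene", "condition", "replicate", "cq")])
  combined <- dplyr::mutate(fc(tab2, "..combined.."),
                            reference = "combined", .before = 1L)
  dplyr::bind_rows(per_ref, combined)
}
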