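#' Write a dataset as PLINK text files plus a pedigree table
#'
#' Writes `<prefix>.ped` / `<prefix>.map` (biallelic text genotypes, missing
#' coded `0 0`, alleles coded 1/2) and `<prefix>.fam.tsv` (id, sire, dam,
#' sex). Coordinates are 1-based bp.
#'
#' @param sim An `hs_sim` object, or a list with `genotypes`, `map`,
#'   `pedigree` in the same shapes.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(sim, prefix) {
  G <- sim$genotypes; map <- sim$map; ped <- sim$pedigree
  a1 <- matrix("0", nrow(G), ncol(G)); a2 <- a1
  a1[!is.na(G) & G >= 1] <- "2"; a1[!is.na(G) & G == 0] <- "1"
  a2[!is.na(G) & G == 2] <- "2"; a2[!is.na(G) & G <= 1] <- "1"
  inter <- matrix("", nrow(G), 2L * ncol(G))
  inter[, seq(1, 2L * ncol(G), 2L)] <- a1
  inter[, seq(2, 2L * ncol(G), 2L)] <- a2
  sex_code <- ifelse(ped$sex == "male", 1L, ifelse(ped$sex == "female", 2L, 0L))
  pedcols <- data.frame(fam = 1L, id = ped$id,
                        pat = ifelse(is.na(ped$sire), "0", ped$sire),
                        mat = ifelse(is.na(ped$dam), "0", ped$dam),
                        sex = sex_code, pheno = -9L)
  write.table(cbind(pedcols, inter), paste0(prefix, ".ped"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(map$chr, map$marker, 0, map$bp),
              paste0(prefix, ".map"),
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(ped, paste0(prefix, ".fam.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read PLINK text genotypes
#'
#' Reads `<prefix>.ped` / `<prefix>.map` written by [write_plink()] (or any
#' biallelic 1/2-coded text PLINK pair). Markers are re-ordered by
#' (chromosome, bp) with a warning if the map is unsorted; `0 0` becomes the
#' missing sentinel `NA`.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A list with `genotypes` (individuals x markers integer matrix),
#'   `map` (tibble marker, chr, bp) and `pedigree`.
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chr", "marker", "cm", "bp"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer"))
  assert_that(!anyDuplicated(map$marker), "duplicated marker ids in .map")
  ord <- order(map$chr, map$bp)
  if (!identical(ord, seq_len(nrow(map)))) {
    warning("map not sorted by (chr, bp); re-ordering markers")
  }
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    colClasses = "character")
  q <- nrow(map)
  assert_that(ncol(ped) == 6L + 2L * q, "ped/map column mismatch")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  assert_that(all(al %in% c("0", "1", "2")),
              "allele codes beyond biallelic 0/1/2")
  a1 <- al[, seq(1, 2L * q, 2L), drop = FALSE]
  a2 <- al[, seq(2, 2L * q, 2L), drop = FALSE]
  G <- (a1 == "2") + (a2 == "2")
  G[a1 == "0" | a2 == "0"] <- NA
  storage.mode(G) <- "integer"
  rownames(G) <- ped[, 2L]
  colnames(G) <- map$marker
  G <- G[, ord, drop = FALSE]
  map <- map[ord, ]
  fam <- paste0(prefix, ".fam.tsv")
  pedigree <- if (file.exists(fam)) {
    tibble::as_tibble(read.table(fam, header = TRUE, sep = "\t",
                                 colClasses = c("character", "character",
                                                "character", "character"),
                                 na.strings = "NA"))
  } else {
    tibble::tibble(id = ped[, 2L],
                   sire = ifelse(ped[, 3L] == "0", NA_character_, ped[, 3L]),
                   dam = ifelse(ped[, 4L] == "0", NA_character_, ped[, 4L]),
                   sex = c("0" = "unknown", "1" = "male",
                           "2" = "female")[ped[, 5L]])
  }
  list(genotypes = G,
       map = tibble::tibble(marker = map$marker, chr = map$chr, bp = map$bp),
       pedigree = pedigree)
}

#' Filter markers on minor allele frequency
#'
#' MAF is computed on non-missing calls over all genotyped individuals;
#' markers with MAF at or below the threshold (including monomorphic markers)
#' are removed.
#'
#' @param genotypes Individuals x markers 0/1/2/`NA` matrix.
#' @param threshold MAF threshold; markers are kept when `maf > threshold`.
#' @return A list with the filtered `genotypes` and a `report` tibble
#'   (`marker`, `maf`, `kept`).
#' @export
maf_filter <- function(genotypes, threshold = 0.01) {
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0
  keep <- maf > threshold
  assert_that(any(keep), "MAF filter removed every marker")
  list(genotypes = genotypes[, keep, drop = FALSE],
       report = tibble::tibble(marker = colnames(genotypes),
                               maf = unname(maf), kept = unname(keep)))
}

# opposing-homozygote conflicts of progeny against one parent
parent_conflicts <- function(G, prog, par) {
  has <- !is.na(par) & par %in% rownames(G)
  conflict <- matrix(FALSE, length(prog), ncol(G))
  comparable <- matrix(FALSE, length(prog), ncol(G))
  if (any(has)) {
    P <- G[prog[has], , drop = FALSE]
    Q <- G[par[has], , drop = FALSE]
    ok <- !is.na(P) & !is.na(Q)
    comparable[has, ] <- ok
    conflict[has, ] <- ok & ((P == 0 & Q == 2) | (P == 2 & Q == 0))
  }
  list(conflict = conflict, comparable = comparable)
}

#' Mendelian-inconsistency screen on half-sib data
#'
#' Counts opposing-homozygote conflicts of each progeny against its genotyped
#' sire and dam. Whole families whose conflict rate exceeds `family_max` are
#' removed first, then markers whose fraction of conflicted families exceeds
#' `marker_max`, and finally any remaining conflicting progeny genotype is set
#' to missing (the parent call is kept).
#'
#' @param genotypes Individuals x markers matrix.
#' @param pedigree Tibble with `id`, `sire`, `dam`.
#' @param family_max Maximum tolerated per-family conflict rate (default 5%).
#' @param marker_max Maximum tolerated per-marker rate of conflicted families
#'   (default 10%).
#' @return A list with cleaned `genotypes`, `family_rates`, `marker_rates`
#'   and a `report` of removal counts.
#' @export
mendel_check <- function(genotypes, pedigree, family_max = 0.05,
                         marker_max = 0.10) {
  prog <- pedigree$id[!is.na(pedigree$sire) | !is.na(pedigree$dam)]
  prog <- intersect(prog, rownames(genotypes))
  ped <- pedigree[match(prog, pedigree$id), ]
  cs <- parent_conflicts(genotypes, prog, ped$sire)
  cd <- parent_conflicts(genotypes, prog, ped$dam)
  conflict <- cs$conflict | cd$conflict
  comparable <- cs$comparable | cd$comparable
  fam <- ifelse(is.na(ped$sire), paste0("dam:", ped$dam), ped$sire)
  n_conf <- rowSums(conflict); n_comp <- rowSums(comparable)
  fam_rate <- tapply(n_conf, fam, sum) / pmax(tapply(n_comp, fam, sum), 1)
  bad_fam <- names(fam_rate)[fam_rate > family_max]
  keep_prog <- !(fam %in% bad_fam)
  # per marker: conflicted families / families informative at the marker
  fam_f <- factor(fam[keep_prog])
  conf_by_fam <- rowsum(conflict[keep_prog, , drop = FALSE] + 0, fam_f)
  comp_by_fam <- rowsum(comparable[keep_prog, , drop = FALSE] + 0, fam_f)
  marker_rate <- colSums(conf_by_fam > 0) / pmax(colSums(comp_by_fam > 0), 1)
  bad_marker <- marker_rate > marker_max
  G <- genotypes
  drop_ind <- prog[!keep_prog]
  G <- G[setdiff(rownames(G), drop_ind), !bad_marker, drop = FALSE]
  # zero remaining conflicting progeny calls
  left_prog <- intersect(prog[keep_prog], rownames(G))
  zeroed <- 0L
  if (length(left_prog)) {
    pedl <- pedigree[match(left_prog, pedigree$id), ]
    cs2 <- parent_conflicts(G, left_prog, pedl$sire)
    cd2 <- parent_conflicts(G, left_prog, pedl$dam)
    conf2 <- cs2$conflict | cd2$conflict
    zeroed <- sum(conf2)
    if (zeroed > 0) {
      M <- G[left_prog, , drop = FALSE]
      M[conf2] <- NA_integer_
      G[left_prog, ] <- M
    }
  }
  list(genotypes = G,
       family_rates = tibble::tibble(family = names(fam_rate),
                                     rate = as.numeric(fam_rate)),
       marker_rates = tibble::tibble(marker = colnames(genotypes),
                                     rate = unname(marker_rate)),
       report = tibble::tibble(families_removed = length(bad_fam),
                               progeny_removed = length(drop_ind),
                               markers_removed = sum(bad_marker),
                               genotypes_zeroed = zeroed))
}

#' Drop blacklisted markers
#'
#' @param genotypes Individuals x markers matrix.
#' @param blacklist Character vector of marker ids (e.g. misplacement
#'   candidates); unknown ids are ignored with a warning.
#' @return The genotype matrix without the listed markers.
#' @export
apply_blacklist <- function(genotypes, blacklist) {
  if (length(blacklist) == 0) return(genotypes)
  unknown <- setdiff(blacklist, colnames(genotypes))
  if (length(unknown))
    warning(length(unknown), " blacklisted marker(s) not in the panel")
  genotypes[, setdiff(colnames(genotypes), blacklist), drop = FALSE]
}

#' Summarise a genotyped half-sib dataset
#'
#' Reports the counts conventionally used to describe half-sib genotype data:
#' total genotyped individuals, paternal half-sib families, genotyped sires
#' and dams, and the same after reduction to families with at least
#' `min_progeny` genotyped progeny.
#'
#' @param genotypes Individuals x markers matrix.
#' @param pedigree Tibble with `id`, `sire`, `dam`, `sex`.
#' @param min_progeny Family-size threshold for the reduced counts.
#' @return A one-row tibble with `n_t`, `N`, `n_s`, `n_d`, `n_t_star`,
#'   `N_star`, `q` and `missing`.
#' @export
dataset_summary <- function(genotypes, pedigree, min_progeny = 30) {
  ids <- rownames(genotypes)
  ped <- pedigree[pedigree$id %in% ids, ]
  prog <- ped[!is.na(ped$sire), ]
  fam_sizes <- table(prog$sire)
  sires <- intersect(unique(prog$sire), ids)
  dams <- intersect(unique(prog$dam[!is.na(prog$dam)]), ids)
  big <- names(fam_sizes)[fam_sizes >= min_progeny]
  in_big <- prog$id[prog$sire %in% big]
  tibble::tibble(
    n_t = length(ids),
    N = length(fam_sizes),
    n_s = length(sires),
    n_d = length(dams),
    n_t_star = length(in_big) + sum(big %in% ids),
    N_star = length(big),
    q = ncol(genotypes),
    missing = mean(is.na(genotypes))
  )
}
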