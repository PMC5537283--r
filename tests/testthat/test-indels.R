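toy_locus <- function() {
  # 60 nt, ATG at 12, CDS of 45 nt; fixed sequence so residue-level
  # expectations are stable
  reference_locus(
    "toy",
    paste0("GGCCTTAACGTT", "ATGGCTTCTAAAGGGTTTCCCGAAGATCATATTCTGGTGAAA",
           "CCGGTA"),
    cds_start = 12L, cds_frame_len = 42L)
}

test_that("a wildtype clone yields a wildtype call with zero net change", {
  locus <- toy_locus()
  call <- call_indel(locus$seq, locus)
  expect_identical(call$frame_class, "wildtype")
  expect_identical(call$net_change, 0L)
  expect_identical(call$protein_consequence, "")
})

test_that("constructed deletions and insertions are recovered with correct frame", {
  locus <- toy_locus()
  r <- locus$seq
  # 3-base deletion at position 30 (0-based): in frame
  del3 <- paste0(substr(r, 1, 30), substr(r, 34, nchar(r)))
  c1 <- call_indel(del3, locus)
  expect_identical(c1$net_change, -3L)
  expect_identical(c1$frame_class, "in_frame")
  # 1-base insertion: frameshift
  ins1 <- paste0(substr(r, 1, 30), "A", substr(r, 31, nchar(r)))
  c2 <- call_indel(ins1, locus)
  expect_identical(c2$net_change, 1L)
  expect_identical(c2$frame_class, "frameshift")
  expect_identical(c2$protein_consequence, "[frameshift]")
  # deletion spanning the start ATG: start_loss
  delatg <- paste0(substr(r, 1, 11), substr(r, 17, nchar(r)))
  c3 <- call_indel(delatg, locus)
  expect_identical(c3$frame_class, "start_loss")
})

test_that("repeat-context deletions are left-aligned, matching placement enumeration", {
  set.seed(41)
  for (rep in 1:20) {
    # build a reference with a planted tandem repeat, delete one unit
    unit <- random_dna(sample(2:4, 1))
    copies <- sample(2:4, 1)
    left <- random_dna(30); right <- random_dna(30)
    ref <- paste0("ATG", left, strrep(unit, copies), right)
    locus <- reference_locus("rep", ref, cds_start = 0L,
                             cds_frame_len = (nchar(ref) %/% 3L) * 3L)
    d0 <- 3L + nchar(left) + nchar(unit) * (copies - 1L)  # delete last unit
    clone <- paste0(substr(ref, 1, d0), substr(ref, d0 + nchar(unit) + 1L,
                                               nchar(ref)))
    call <- call_indel(clone, locus, check_identity = FALSE)
    placements <- enumerate_deletion_placements(ref, clone)
    expect_identical(call$del_start, min(placements))
    expect_identical(call$del_end, min(placements) + nchar(unit))
    expect_identical(call$ins_seq, "")
  }
})

test_that("compound and substitution-run descriptions agree in net change and frame", {
  locus <- toy_locus()
  r <- locus$seq
  # replace 6 reference bases at 24 with 3 new bases (compound)
  clone <- paste0(substr(r, 1, 24), "TTT", substr(r, 31, nchar(r)))
  call <- call_indel(clone, locus, check_identity = FALSE)
  expect_identical(call$net_change, -3L)
  expect_identical(call$frame_class, "in_frame")
  expect_true(call$del_end - call$del_start - nchar(call$ins_seq) == 3L)
})

test_that("frameshift arithmetic holds for random indels away from the start codon", {
  set.seed(42)
  locus <- make_random_locus(400, cds_start = 0L)
  r <- locus$seq
  for (rep in 1:50) {
    d0 <- sample(50:300, 1)
    dlen <- sample(0:12, 1)
    ilen <- sample(0:8, 1)
    if (dlen == 0 && ilen == 0) next
    ins <- if (ilen) random_dna(ilen) else ""
    clone <- paste0(substr(r, 1, d0), ins, substr(r, d0 + dlen + 1, nchar(r)))
    call <- call_indel(clone, locus, check_identity = FALSE)
    net <- ilen - dlen
    expect_identical(call$net_change, net)
    if (net %% 3L != 0L) {
      expect_identical(call$frame_class, "frameshift")
    } else if (net == 0L && clone == r) {
      expect_identical(call$frame_class, "wildtype")
    } else {
      expect_true(call$frame_class %in% c("in_frame", "wildtype"))
    }
  }
})

test_that("clones that do not match the locus are rejected", {
  locus <- toy_locus()
  set.seed(43)
  expect_error(call_indel(random_dna(60), locus), "does not match")
})

test_that("protein consequence reports the minimal changed residue run", {
  locus <- toy_locus()
  r <- locus$seq
  # in-frame deletion of one codon directly after the ATG
  del_codon <- paste0(substr(r, 1, 15), substr(r, 19, nchar(r)))
  call <- call_indel(del_codon, locus, check_identity = FALSE)
  expect_identical(call$frame_class, "in_frame")
  expect_match(call$protein_consequence, "->")
  # consequence agrees with an exhaustive translate-and-diff oracle
  wt_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(r, 13, 54)), no.init.codon = TRUE))
  mut_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(del_codon, 13, 51)), no.init.codon = TRUE))
  want <- oracle_protein_diff(wt_aa, mut_aa)
  expect_identical(call$protein_consequence,
                   paste0(want$wt, "->", want$mut))
})

test_that("a 21-nt-for-9-nt compound replacement after the ATG changes 7 residues to 3", {
  set.seed(44)
  locus <- make_random_locus(300, cds_start = 12L, id = "arith")
  r <- locus$seq
  repeat {  # ensure the inserted run translates to 3 residues unlike WT
    ins <- random_dna(9)
    clone <- paste0(substr(r, 1, 15), ins, substr(r, 37, nchar(r)))
    call <- call_indel(clone, locus, check_identity = FALSE)
    cons <- call$protein_consequence
    if (nchar(sub("->.*", "", cons)) == 7L) break
  }
  expect_identical(call$frame_class, "in_frame")
  expect_identical(call$net_change, -12L)
  parts <- strsplit(cons, "->", fixed = TRUE)[[1]]
  expect_identical(nchar(parts[1]), 7L)
  expect_identical(nchar(parts[2]), 3L)
})

test_that("frame-conserving events outside the CDS carry an empty consequence", {
  locus <- toy_locus()
  r <- locus$seq
  # 3-base deletion entirely in the 5' UTR (positions 3..5)
  clone <- paste0(substr(r, 1, 3), substr(r, 7, nchar(r)))
  call <- call_indel(clone, locus, check_identity = FALSE)
  expect_identical(call$frame_class, "in_frame")
  expect_identical(call$protein_consequence, "")
})

test_that("paralog assignment follows diagnostic bases and reports ties as ambiguous", {
  base <- paste0("ATG", strrep("GATTACAGGC", 12))
  sL <- strsplit(base, "")[[1]]; sL[50] <- "C"; sL[80] <- "C"
  s2 <- strsplit(base, "")[[1]]; s2[50] <- "T"; s2[80] <- "T"
  rho_L <- reference_locus("rho.L", paste(sL, collapse = ""), 0L,
                           diagnostic_positions = list(`49` = "C", `79` = "C"))
  rho_2L <- reference_locus("rho.2.L", paste(s2, collapse = ""), 0L,
                            diagnostic_positions = list(`49` = "T", `79` = "T"))
  loci <- list(rho_L, rho_2L)
  expect_identical(assign_paralog(rho_L$seq, loci)$locus_id, "rho.L")
  expect_identical(assign_paralog(rho_2L$seq, loci)$locus_id, "rho.2.L")
  # a clone mutated at one diagnostic site (matches neither) is decided
  # from the remaining site
  sm <- strsplit(rho_L$seq, "")[[1]]; sm[50] <- "G"
  res <- assign_paralog(paste(sm, collapse = ""), loci)
  expect_identical(res$locus_id, "rho.L")
  expect_identical(unname(res$support["rho.L"]), 1L)
  # equal support is ambiguous, never silently broken
  sx <- strsplit(rho_L$seq, "")[[1]]; sx[80] <- "T"
  expect_identical(assign_paralog(paste(sx, collapse = ""), loci)$locus_id,
                   "ambiguous")
  # a clone whose edit deletes every diagnostic base is ambiguous too
  del_all <- paste0(substr(rho_L$seq, 1, 40), substr(rho_L$seq, 90, nchar(rho_L$seq)))
  expect_identical(assign_paralog(del_all, loci)$locus_id, "ambiguous")
})

test_that("clone tables list every clone and count identical sequences", {
  locus <- toy_locus()
  r <- locus$seq
  del3 <- paste0(substr(r, 1, 30), substr(r, 34, nchar(r)))
  clones <- c(a = r, b = del3, c = del3)
  calls <- call_indels(clones, locus, check_identity = FALSE)
  expect_identical(nrow(calls), 3L)
  expect_identical(calls$identical_count, c(1L, 2L, 2L))
  # writers round-trip through text formats without dropping clones
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  write_indel_tsv(calls, tsv)
  write_indel_vcf(calls, locus, vcf)
  tab <- read.delim(tsv, comment.char = "#")
  expect_identical(nrow(tab), 3L)
  vcf_lines <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_identical(length(vcf_lines), 2L)  # wildtype clone carries no record
})
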