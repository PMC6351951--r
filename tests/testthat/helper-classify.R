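# Straight-line re-implementation of the published interval tables, kept
# deliberately naive and independent of the package's decision helper.
brute_force_classify <- function(k2, inf_arc, k1, a2, ant, ip) {
  iniv <- function(v, lo, hi) v >= lo && v <= hi
  rp <- iniv(k2, 0.000493763, 0.027066286) && iniv(inf_arc, 108.0939, 214.7204)
  fp <- iniv(k2, 0.029424926, 0.080514181) && iniv(inf_arc, 225.8813, 391.5648)
  c1 <- if (rp && !fp) "RP" else if (fp && !rp) "FP" else "indeterminate"
  ftp <- iniv(k1, 0.000194215, 0.005002445) && iniv(a2, 7.56, 94.89)
  pp <- iniv(k1, 0.006819941, 0.014204314) && iniv(a2, 91.35, 187.54)
  c2 <- if (ftp && pp) {
    # overlap in Area2: the disjoint K1 intervals decide
    if (iniv(k1, 0.000194215, 0.005002445)) "FTP" else "PP"
  } else if (ftp) "FTP" else if (pp) "PP" else "indeterminate"
  ab <- if (ant >= 22.39 && ant < 69.16) "below_average"
        else if (ant >= 69.16 && ant <= 115.9) "above_average"
        else "out_of_range"
  ib <- if (ip >= 2.41 && ip < 42.85) "below_average"
        else if (ip >= 42.85 && ip <= 108.88) "above_average"
        else "out_of_range"
  ta <- if (c2 == "PP" && ab == "above_average") "steatosic"
        else if (c2 == "FTP" && ab == "below_average") "non_steatosic"
        else "indeterminate"
  tb <- if (c1 == "FP" && ib == "above_average") "steatosic"
        else if (c1 == "RP" && ib == "below_average") "non_steatosic"
        else "indeterminate"
  c(c1 = c1, c2 = c2, ab = ab, ib = ib, ta = ta, tb = tb)
}
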