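# Centralized unit conversions.  Element formulas are evaluated in SI
# (Pa, m, s, kg) and converted once at element creation; everything the
# solver and the reporting layer touch is in clinical units:
#   pressure mmHg, flow ml/s (ml/min in reports), volume ml,
#   resistance mmHg.s/ml, inertance mmHg.s^2/ml, compliance ml/mmHg,
#   length cm, diameter mm.

PA_PER_MMHG <- 133.322

# 1 mmHg.s/ml = PA_PER_MMHG / 1e-6 Pa.s/m^3; same factor for inertance.
si_to_clin_resistance <- function(r_si) r_si * 1e-6 / PA_PER_MMHG
si_to_clin_inertance <- function(l_si) l_si * 1e-6 / PA_PER_MMHG

# 1 ml/mmHg = 1e-6 m^3 / PA_PER_MMHG Pa.
si_to_clin_compliance <- function(c_si) c_si * PA_PER_MMHG / 1e-6

pa_to_mmhg <- function(p) p / PA_PER_MMHG
mmhg_to_kpa <- function(p) p * PA_PER_MMHG / 1000

mls_to_mlmin <- function(q) q * 60
mlmin_to_mls <- function(q) q / 60

cm_to_m <- function(x) x * 1e-2
mm_to_m <- function(x) x * 1e-3
mm2_to_m2 <- function(a) a * 1e-6
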