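# camnet model constants, v1.
#
# Constants required by the network that are not part of the printed
# kinetic table shipped in R/parameters.R. Sources are the upstream
# literature the model descends from: the two-state (tense/relaxed)
# lobe kinetics of the nine-state Ca2+-CaM scheme measured by flash
# photolysis (Faas et al. 2011, Nat Neurosci 14:301-304), and the
# CaMKII-PP1 network of He, Kulasiri & Samarasinghe (2016).
#
# Units: on-rates uM^-1 s^-1; off-rates s^-1; concentrations uM.
version: 1
nine_state_rates:
  # N-lobe: fast, low intrinsic affinity; first ion binds in the tense
  # (T) state, the second in the relaxed (R) state.
  kon_NT: 770.0        # uM^-1 s^-1
  koff_NT: 1.6e+5     # s^-1
  kon_NR: 3.2e+4       # uM^-1 s^-1
  koff_NR: 2.2e+4      # s^-1
  # C-lobe: slow, high affinity.
  kon_CT: 84.0         # uM^-1 s^-1
  koff_CT: 2.6e+3       # s^-1
  kon_CR: 25.0         # uM^-1 s^-1
  koff_CR: 6.5         # s^-1
auxiliary:
  Km7: 2.0             # uM, PDE4B Michaelis constant for cAMP
  Km9: 2.0             # uM, PDE4D Michaelis constant for cAMP
  K1: 0.5              # uM, Ca half-saturation of the CaNB gating step
  kB_on: 10.0          # uM^-1 s^-1, Ca association with CaNB (fast gate)
  kI1_on: 10.0         # uM^-1 s^-1, phospho-I-1 association with PP1
  kI1_off: 0.01        # s^-1, I1PP1 dissociation (Kd = 1 nM)
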