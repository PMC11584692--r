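# Parameter notes

Rate constants are in h^-1 (adjusted for reaction order). Protein species
use copies per cell; metabolites, radicals and calcium use relative units
normalized so the quiescent value is 1 (ER calcium 10, BH4 50, AMP 0.2
relative to their partner pools); O2 is a fraction (0.21 control) and
glucose mmol/L (5.05 control).

Rate constants marked as "balanced" are solved at build time so the
declared baseline is an exact steady state under the control environment;
the remaining constants set response timescales and gains and were chosen
so the qualitative-dynamics suite (succinate accumulation/oxidation, ROS
burst, pAMPK double peak, p53 rise-and-return, marker monotonicities)
holds.

## Hill coefficients above 1 (each requires justification)

- `kp_IKK_ROS` regulator ROS, n = 4, K = 4x baseline: switch-like redox
  activation of IKK. Needs a high threshold and steep response so the
  reoxygenation ROS burst drives NFkB strongly while baseline ROS and the
  mild OGD-phase ROS dip contribute almost nothing (a shallow response
  would let the OGD-phase ROS dip depress cytokine output below control).
- `kox_BH4` regulator ROS, n = 4, K = 2x baseline: BH4 oxidation to BH2 is
  modeled as burst-gated so the BH2 pool integrates the reoxygenation burst
  and sustains moderately elevated ROS afterwards, reproducing persistent
  free-radical elevation and progressive tight-junction loss.
- `kt_Casp3_self` regulator Casp3, n = 4, K = 8x baseline: caspase
  self-amplification with a high threshold produces the bistable commitment
  that makes apoptosis reversible after short OGD but irreversible after
  24 h OGD.
- `kp_AMPK_Ca` regulator cytosolic calcium, n = 3, K = 2x baseline: the
  calcium-mediated second phase of AMPK activation must remain quiet at
  baseline calcium and switch on during the post-reoxygenation calcium
  elevation to produce the distinct second pAMPK peak 4-8 h after
  reoxygenation.
- Remaining n = 2 regulators (kinase cascades, transcriptional Hill terms,
  O2 sensing in SDH flux): mild ultrasensitivity standard for
  double-phosphorylation/cooperative binding steps; n = 1 (Michaelis form)
  is used wherever a graded response suffices.

## Field-notation parameter aliases

ASCII identifiers stand for the field's notation: `kp_IKK_ROS` =
"kp_IKK(ROS)", `kd_IkB_mRNA` = "kd_IKB(mrna)", `kt_HIF1a`/`kon_HIF1a` and
`koh_HIF2a`/`kin_HIF2a` for the corresponding Greek-letter forms.
`VEGFR_pY1173` is accepted as an alias of `VEGFR_pY1175`.
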