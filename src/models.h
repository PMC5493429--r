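#ifndef IKURSIM_MODELS_H
#define IKURSIM_MODELS_H

#include "common.h"

// A cell model exposes its state size, a default initial state, a
// voltage-LUT builder for a given parameter set and step size, and a step
// function advancing the full state by dt.  i_ext is an external current in
// pA/pF with depolarising sign positive (stimulus and/or diffusion term).
struct CellModel {
  int n_state;
  int n_lut;
  void (*default_state)(double* y);
  void (*build_lut)(Lut& lut, const double* p, double dt);
  void (*step)(double* y, const double* p, const Lut& lut, double dt,
               double i_ext);
};

const CellModel& ctm_model();
const CellModel& grandi_model();

inline const CellModel& get_model(int id) {
  if (id == 0) return ctm_model();
  return grandi_model();
}

// shared parameter-vector indices -------------------------------------------

// Courtemanche-lineage parameter layout
enum {
  CP_GNA = 0, CP_GTO, CP_GCAL, CP_GKR, CP_GKS, CP_GK1, CP_GKUR,
  CP_GNAK, CP_GNCX, CP_GUP, CP_KUPF,
  CP_IKUR_MODE,     // 0 = native gating, 1 = new I_Kur formulation
  CP_ACT_N, CP_ACT_VH1, CP_ACT_K1, CP_ACT_VH2, CP_ACT_K2,
  CP_INACT_VH, CP_INACT_K, CP_INACT_AMP, CP_INACT_FLOOR,
  CP_DSHIFT, CP_XSSHIFT,
  CP_NPAR
};

// Grandi-lineage parameter layout
enum {
  GP_AF = 0, GP_ISO,
  GP_GNA, GP_GTO, GP_GCAL, GP_GKR, GP_GKS, GP_GK1, GP_GKUR,
  GP_GNCX, GP_GNAK, GP_GUP,
  GP_KUR_AVH, GP_KUR_AK, GP_KUR_IVH, GP_KUR_IK, GP_KUR_MA,
  GP_NPAR
};

#endif
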