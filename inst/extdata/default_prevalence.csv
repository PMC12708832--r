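entity,region,year,women_share_cases
HeartFailure,ANY,ANY,0.50
HFrEF,ANY,ANY,0.42
HFpEF,ANY,ANY,0.57
IschemicHeartDisease,ANY,ANY,0.45
OtherCVD,ANY,ANY,0.50
Stroke,ANY,ANY,0.52
SystemicHypertension,ANY,ANY,0.52
AtrialFibrillation,ANY,ANY,0.47
Cardiomyopathy,ANY,ANY,0.35
LowerExtremity,ANY,ANY,0.40
ValveEndocarditis,ANY,ANY,0.45
PulmonaryHypertension,ANY,ANY,0.60
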