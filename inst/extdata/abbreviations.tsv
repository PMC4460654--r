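kmph	kph
kmh	kph
pt	patient
ptn	patient
frac	fracture
fx	fracture
lac	laceration
lt	left
rt	right
abdo	abdomen
approx	approximately
mva	vehicle
bldg	building
hosp	hospital
med	medication
meds	medication
temp	temperature
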