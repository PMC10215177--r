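species,source,n,index,low,high
M. aurascens,Kim,10,BM,5.70,7.10
M. aurascens,Kim,10,FL,34.71,38.21
M. aurascens,Kim,10,LHB,42.64,46.40
M. aurascens,Kim,10,TBL,16.22,18.04
M. aurascens,Kim,10,TL,41.03,45.26
M. aurascens,Kim,10,EL,13.06,14.98
M. aurascens,Kim,10,TRL,7.64,8.88
M. aurascens,Kim,10,LHF,6.42,7.68
M. aurascens,Oh,7,FL,33.80,37.30
M. aurascens,Oh,7,LHB,40.80,48.00
M. aurascens,Oh,7,TBL,15.10,17.47
M. aurascens,Oh,7,TL,36.00,42.00
M. aurascens,Oh,7,EL,11.00,15.00
M. aurascens,Oh,7,TRL,6.30,9.00
M. aurascens,Oh,7,LHF,7.00,10.00
M. davidii,davidii_ref,3,BM,4.50,5.00
M. davidii,davidii_ref,3,FL,34.00,34.54
M. davidii,davidii_ref,3,LHB,38.00,41.00
M. davidii,davidii_ref,3,TBL,15.00,15.11
M. davidii,davidii_ref,3,TL,31.00,35.00
M. davidii,davidii_ref,3,EL,11.00,15.00
M. davidii,davidii_ref,1,EW,5.51,5.51
M. davidii,davidii_ref,1,TRL,5.09,5.09
M. davidii,davidii_ref,3,LHF,7.62,9.50
M. davidii,davidii_ref,1,McIII,31.94,31.94
M. davidii,davidii_ref,1,III1,12.02,12.02
M. davidii,davidii_ref,1,III2,9.06,9.06
M. davidii,davidii_ref,1,McIV,30.08,30.08
M. davidii,davidii_ref,1,McV,32.67,32.67
M. davidii,davidii_ref,1,V1,8.37,8.37
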