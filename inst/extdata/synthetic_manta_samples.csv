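"sample_id","species","sex","year","d13C","d15N","c_to_n"
"con001","Manta birostris","m",2012,-15.53,11.17,3.08
"con002","Manta birostris","f",2012,-18.15,8.91,3.46
"con003","Manta birostris","m",2012,-15.71,9.17,3.16
"con004","Manta birostris","f",2012,-18.06,8.71,3.01
"con005","Manta birostris","m",2013,-18.49,8.54,2.95
"con006","Manta birostris","f",2013,-16.08,11.34,3.19
"con007","Manta birostris","m",2013,-17.03,11.79,3.22
"con008","Manta birostris","f",2013,-17.85,10.2,3.1
"con009","Manta birostris","m",2014,-16.24,11.3,3.41
"con010","Manta birostris","f",2014,-15.45,13.32,3.3
"con011","Manta birostris","m",2014,-16.9,11.9,3.38
"con012","Manta birostris","f",2014,-16.12,10.85,3.63
"tow001","zooplankton",,,-20.4,6.14,4.85
"tow002","zooplankton",,,-20.98,8.73,4.34
"tow003","zooplankton",,,-20.56,8.55,3.86
"tow004","zooplankton",,,-21.45,7.83,4.64
"tow005","zooplankton",,,-20.53,7.62,3.49
"tow006","zooplankton",,,-19.45,6.68,4.95
"tow007","zooplankton",,,-20.64,7.82,4.12
"tow008","zooplankton",,,-20,9.04,4.15
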