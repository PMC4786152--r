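name,specification,details
vartable,basic_cd4,Patient-level table with both indicators
var1,aids_y == 1,Indicator 1: clinical AIDS at enrollment
var2,cd4_base < 200,Indicator 2: baseline CD4 below 200 cells/uL
vartablesubset,"aids_y in (0,1) and not missing(cd4_base)",Rows entering the plot
eventdate,enrol_d,Date that assigns each subject to a period
eventperiod,year,Frame period (month / quarter / year)
group,site,One bubble per group per period
var1label1,AIDS,
var1label0,no AIDS,
var2label1,<200,
var2label0,200+,
var1label,Proportion with clinical AIDS,
var2label,Proportion CD4<200 at enrollment in HIV care,
minnum,5,Minimum subjects for a bubble to be drawn
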