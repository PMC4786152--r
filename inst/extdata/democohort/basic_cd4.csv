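"patient","site","country","enrol_d","aids_y","cd4_base"
"P00001","andes","PER","2007-03-18",0,198
"P00002","carib","HTI","2008-06-20",9,177
"P00003","vanguard","BRA","2011-02-05",0,412
"P00004","andes","PER","2010-12-14",0,274
"P00005","vanguard","BRA","2009-07-22",1,231
"P00006","carib","HTI","2004-10-15",0,418
"P00007","andes","PER","2010-12-17",0,341
"P00008","carib","HTI","2002-12-07",1,146
"P00009","vanguard","BRA","2007-08-30",1,219
"P00010","carib","HTI","2007-11-26",1,242
"P00011","carib","HTI","2010-12-06",0,171
"P00012","vanguard","BRA","2010-02-01",0,185
"P00013","vanguard","BRA","2010-01-30",0,229
"P00014","vanguard","BRA","2002-03-19",1,106
"P00015","andes","PER","2004-05-05",1,66
"P00016","vanguard","BRA","2007-10-31",0,238
"P00017","carib","HTI","2003-09-27",0,409
"P00018","carib","HTI","2007-08-19",0,271
"P00019","andes","PER","2010-02-13",0,185
"P00020","vanguard","BRA","2009-08-15",0,129
"P00021","andes","PER","2007-03-10",0,72
"P00022","andes","PER","2005-12-25",0,150
"P00023","carib","HTI","2004-04-21",9,557
"P00024","andes","PER","2011-07-01",0,154
"P00025","vanguard","BRA","2002-11-22",0,223
"P00026","vanguard","BRA","2002-12-18",1,157
"P00027","andes","PER","2006-12-30",0,175
"P00028","vanguard","BRA","2010-11-09",1,226
"P00029","vanguard","BRA","2011-04-13",1,318
"P00030","vanguard","BRA","2006-09-06",0,135
"P00031","carib","HTI","2003-12-12",0,171
"P00032","andes","PER","2006-03-23",0,144
"P00033","carib","HTI","2007-06-25",1,98
"P00034","andes","PER","2003-06-25",1,325
"P00035","vanguard","BRA","2010-05-15",0,167
"P00036","carib","HTI","2006-01-13",0,98
"P00037","vanguard","BRA","2009-04-10",9,310
"P00038","carib","HTI","2004-12-06",0,252
"P00039","andes","PER","2005-03-27",0,797
"P00040","andes","PER","2003-09-25",0,146
"P00041","andes","PER","2004-09-27",1,290
"P00042","vanguard","BRA","2005-05-20",9,230
"P00043","andes","PER","2005-03-15",0,561
"P00044","vanguard","BRA","2005-10-07",0,411
"P00045","andes","PER","2011-05-18",0,492
"P00046","andes","PER","2008-03-07",1,229
"P00047","vanguard","BRA","2003-04-26",1,344
"P00048","vanguard","BRA","2011-11-19",1,216
"P00049","vanguard","BRA","2008-07-16",0,167
"P00050","vanguard","BRA","2008-03-21",9,214
"P00051","carib","HTI","2007-07-11",0,96
"P00052","andes","PER","2011-08-18",0,189
"P00053","vanguard","BRA","2004-01-01",0,266
"P00054","vanguard","BRA","2006-02-14",1,55
"P00055","carib","HTI","2008-10-20",0,187
"P00056","carib","HTI","2010-04-22",1,262
"P00057","vanguard","BRA","2009-04-12",0,846
"P00058","vanguard","BRA","2007-11-21",0,103
"P00059","carib","HTI","2010-12-15",0,175
"P00060","andes","PER","2002-01-07",0,112
"P00061","carib","HTI","2005-12-07",0,502
"P00062","vanguard","BRA","2003-01-30",9,112
"P00063","andes","PER","2006-04-23",1,133
"P00064","carib","HTI","2008-09-01",0,91
"P00065","andes","PER","2003-10-27",0,246
"P00066","andes","PER","2011-12-23",1,204
"P00067","carib","HTI","2002-12-31",0,146
"P00068","carib","HTI","2011-03-03",0,330
"P00069","carib","HTI","2007-04-17",0,486
"P00070","andes","PER","2011-04-16",0,99
"P00071","vanguard","BRA","2006-08-06",0,140
"P00072","andes","PER","2008-04-13",1,239
"P00073","carib","HTI","2003-08-17",1,337
"P00074","carib","HTI","2003-10-09",1,20
"P00075","vanguard","BRA","2006-04-09",0,196
"P00076","carib","HTI","2008-04-24",1,291
"P00077","vanguard","BRA","2009-12-20",1,147
"P00078","andes","PER","2009-10-27",0,519
"P00079","vanguard","BRA","2011-08-03",1,249
"P00080","vanguard","BRA","2005-03-04",0,129
"P00081","vanguard","BRA","2004-09-05",1,225
"P00082","vanguard","BRA","2011-08-23",0,592
"P00083","vanguard","BRA","2002-12-15",0,128
"P00084","vanguard","BRA","2005-01-28",0,183
"P00085","vanguard","BRA","2006-11-22",1,55
"P00086","andes","PER","2002-09-20",1,69
"P00087","vanguard","BRA","2008-04-22",0,156
"P00088","vanguard","BRA","2011-03-30",0,306
"P00089","andes","PER","2009-05-22",0,216
"P00090","carib","HTI","2003-06-15",1,277
"P00091","vanguard","BRA","2010-01-23",0,106
"P00092","carib","HTI","2002-10-08",0,210
"P00093","andes","PER","2004-10-18",0,890
"P00094","carib","HTI","2009-04-12",9,202
"P00095","vanguard","BRA","2011-01-16",0,90
"P00096","vanguard","BRA","2009-04-05",1,748
"P00097","carib","HTI","2005-07-15",0,430
"P00098","carib","HTI","2003-10-10",0,303
"P00099","andes","PER","2010-03-29",1,210
"P00100","carib","HTI","2008-03-24",1,224
"P00101","andes","PER","2006-10-09",0,131
"P00102","andes","PER","2010-09-14",0,267
"P00103","carib","HTI","2002-11-15",0,149
"P00104","carib","HTI","2003-06-09",0,451
"P00105","andes","PER","2003-04-09",1,219
"P00106","andes","PER","2006-04-11",1,229
"P00107","carib","HTI","2010-03-31",1,85
"P00108","carib","HTI","2005-08-29",0,270
"P00109","carib","HTI","2007-01-03",1,219
"P00110","vanguard","BRA","2008-12-03",0,459
"P00111","vanguard","BRA","2011-11-04",1,209
"P00112","carib","HTI","2006-06-18",1,88
"P00113","vanguard","BRA","2004-11-16",0,119
"P00114","carib","HTI","2008-12-12",0,1280
"P00115","andes","PER","2004-04-04",0,79
"P00116","andes","PER","2004-10-04",0,165
"P00117","carib","HTI","2003-08-31",0,254
"P00118","carib","HTI","2010-06-05",0,231
"P00119","carib","HTI","2003-10-02",0,339
"P00120","andes","PER","2010-02-09",0,463
"P00121","carib","HTI","2008-04-29",0,274
"P00122","andes","PER","2005-09-28",0,529
"P00123","andes","PER","2003-09-26",0,157
"P00124","vanguard","BRA","2004-12-28",1,245
"P00125","vanguard","BRA","2005-03-16",0,307
"P00126","andes","PER","2011-03-10",9,304
"P00127","vanguard","BRA","2009-09-05",9,135
"P00128","carib","HTI","2003-03-21",0,107
"P00129","carib","HTI","2007-05-10",0,619
"P00130","vanguard","BRA","2008-07-26",0,86
"P00131","carib","HTI","2004-07-14",0,473
"P00132","andes","PER","2010-12-11",0,402
"P00133","carib","HTI","2009-02-12",1,236
"P00134","andes","PER","2003-08-18",0,202
"P00135","andes","PER","2002-04-20",9,130
"P00136","vanguard","BRA","2007-08-07",1,405
"P00137","vanguard","BRA","2002-05-14",1,142
"P00138","andes","PER","2004-04-30",0,235
"P00139","carib","HTI","2002-03-06",1,200
"P00140","andes","PER","2009-11-20",1,214
"P00141","andes","PER","2002-08-09",1,194
"P00142","andes","PER","2008-03-05",1,31
"P00143","andes","PER","2007-12-01",1,110
"P00144","vanguard","BRA","2010-10-10",0,322
"P00145","vanguard","BRA","2007-04-07",1,255
"P00146","andes","PER","2006-01-26",0,93
"P00147","andes","PER","2008-12-19",1,39
"P00148","vanguard","BRA","2007-04-13",0,98
"P00149","andes","PER","2010-07-16",0,141
"P00150","andes","PER","2011-04-11",0,466
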