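"patient","site","country","enrol_d","aids_y"
"P00001","andes","PER","2007-03-18",0
"P00002","carib","HTI","2008-06-20",9
"P00003","vanguard","BRA","2011-02-05",0
"P00004","andes","PER","2010-12-14",0
"P00005","vanguard","BRA","2009-07-22",1
"P00006","carib","HTI","2004-10-15",0
"P00007","andes","PER","2010-12-17",0
"P00008","carib","HTI","2002-12-07",1
"P00009","vanguard","BRA","2007-08-30",1
"P00010","carib","HTI","2007-11-26",1
"P00011","carib","HTI","2010-12-06",0
"P00012","vanguard","BRA","2010-02-01",0
"P00013","vanguard","BRA","2010-01-30",0
"P00014","vanguard","BRA","2002-03-19",1
"P00015","andes","PER","2004-05-05",1
"P00016","vanguard","BRA","2007-10-31",0
"P00017","carib","HTI","2003-09-27",0
"P00018","carib","HTI","2007-08-19",0
"P00019","andes","PER","2010-02-13",0
"P00020","vanguard","BRA","2009-08-15",0
"P00021","andes","PER","2007-03-10",0
"P00022","andes","PER","2005-12-25",0
"P00023","carib","HTI","2004-04-21",9
"P00024","andes","PER","2011-07-01",0
"P00025","vanguard","BRA","2002-11-22",0
"P00026","vanguard","BRA","2002-12-18",1
"P00027","andes","PER","2006-12-30",0
"P00028","vanguard","BRA","2010-11-09",1
"P00029","vanguard","BRA","2011-04-13",1
"P00030","vanguard","BRA","2006-09-06",0
"P00031","carib","HTI","2003-12-12",0
"P00032","andes","PER","2006-03-23",0
"P00033","carib","HTI","2007-06-25",1
"P00034","andes","PER","2003-06-25",1
"P00035","vanguard","BRA","2010-05-15",0
"P00036","carib","HTI","2006-01-13",0
"P00037","vanguard","BRA","2009-04-10",9
"P00038","carib","HTI","2004-12-06",0
"P00039","andes","PER","2005-03-27",0
"P00040","andes","PER","2003-09-25",0
"P00041","andes","PER","2004-09-27",1
"P00042","vanguard","BRA","2005-05-20",9
"P00043","andes","PER","2005-03-15",0
"P00044","vanguard","BRA","2005-10-07",0
"P00045","andes","PER","2011-05-18",0
"P00046","andes","PER","2008-03-07",1
"P00047","vanguard","BRA","2003-04-26",1
"P00048","vanguard","BRA","2011-11-19",1
"P00049","vanguard","BRA","2008-07-16",0
"P00050","vanguard","BRA","2008-03-21",9
"P00051","carib","HTI","2007-07-11",0
"P00052","andes","PER","2011-08-18",0
"P00053","vanguard","BRA","2004-01-01",0
"P00054","vanguard","BRA","2006-02-14",1
"P00055","carib","HTI","2008-10-20",0
"P00056","carib","HTI","2010-04-22",1
"P00057","vanguard","BRA","2009-04-12",0
"P00058","vanguard","BRA","2007-11-21",0
"P00059","carib","HTI","2010-12-15",0
"P00060","andes","PER","2002-01-07",0
"P00061","carib","HTI","2005-12-07",0
"P00062","vanguard","BRA","2003-01-30",9
"P00063","andes","PER","2006-04-23",1
"P00064","carib","HTI","2008-09-01",0
"P00065","andes","PER","2003-10-27",0
"P00066","andes","PER","2011-12-23",1
"P00067","carib","HTI","2002-12-31",0
"P00068","carib","HTI","2011-03-03",0
"P00069","carib","HTI","2007-04-17",0
"P00070","andes","PER","2011-04-16",0
"P00071","vanguard","BRA","2006-08-06",0
"P00072","andes","PER","2008-04-13",1
"P00073","carib","HTI","2003-08-17",1
"P00074","carib","HTI","2003-10-09",1
"P00075","vanguard","BRA","2006-04-09",0
"P00076","carib","HTI","2008-04-24",1
"P00077","vanguard","BRA","2009-12-20",1
"P00078","andes","PER","2009-10-27",0
"P00079","vanguard","BRA","2011-08-03",1
"P00080","vanguard","BRA","2005-03-04",0
"P00081","vanguard","BRA","2004-09-05",1
"P00082","vanguard","BRA","2011-08-23",0
"P00083","vanguard","BRA","2002-12-15",0
"P00084","vanguard","BRA","2005-01-28",0
"P00085","vanguard","BRA","2006-11-22",1
"P00086","andes","PER","2002-09-20",1
"P00087","vanguard","BRA","2008-04-22",0
"P00088","vanguard","BRA","2011-03-30",0
"P00089","andes","PER","2009-05-22",0
"P00090","carib","HTI","2003-06-15",1
"P00091","vanguard","BRA","2010-01-23",0
"P00092","carib","HTI","2002-10-08",0
"P00093","andes","PER","2004-10-18",0
"P00094","carib","HTI","2009-04-12",9
"P00095","vanguard","BRA","2011-01-16",0
"P00096","vanguard","BRA","2009-04-05",1
"P00097","carib","HTI","2005-07-15",0
"P00098","carib","HTI","2003-10-10",0
"P00099","andes","PER","2010-03-29",1
"P00100","carib","HTI","2008-03-24",1
"P00101","andes","PER","2006-10-09",0
"P00102","andes","PER","2010-09-14",0
"P00103","carib","HTI","2002-11-15",0
"P00104","carib","HTI","2003-06-09",0
"P00105","andes","PER","2003-04-09",1
"P00106","andes","PER","2006-04-11",1
"P00107","carib","HTI","2010-03-31",1
"P00108","carib","HTI","2005-08-29",0
"P00109","carib","HTI","2007-01-03",1
"P00110","vanguard","BRA","2008-12-03",0
"P00111","vanguard","BRA","2011-11-04",1
"P00112","carib","HTI","2006-06-18",1
"P00113","vanguard","BRA","2004-11-16",0
"P00114","carib","HTI","2008-12-12",0
"P00115","andes","PER","2004-04-04",0
"P00116","andes","PER","2004-10-04",0
"P00117","carib","HTI","2003-08-31",0
"P00118","carib","HTI","2010-06-05",0
"P00119","carib","HTI","2003-10-02",0
"P00120","andes","PER","2010-02-09",0
"P00121","carib","HTI","2008-04-29",0
"P00122","andes","PER","2005-09-28",0
"P00123","andes","PER","2003-09-26",0
"P00124","vanguard","BRA","2004-12-28",1
"P00125","vanguard","BRA","2005-03-16",0
"P00126","andes","PER","2011-03-10",9
"P00127","vanguard","BRA","2009-09-05",9
"P00128","carib","HTI","2003-03-21",0
"P00129","carib","HTI","2007-05-10",0
"P00130","vanguard","BRA","2008-07-26",0
"P00131","carib","HTI","2004-07-14",0
"P00132","andes","PER","2010-12-11",0
"P00133","carib","HTI","2009-02-12",1
"P00134","andes","PER","2003-08-18",0
"P00135","andes","PER","2002-04-20",9
"P00136","vanguard","BRA","2007-08-07",1
"P00137","vanguard","BRA","2002-05-14",1
"P00138","andes","PER","2004-04-30",0
"P00139","carib","HTI","2002-03-06",1
"P00140","andes","PER","2009-11-20",1
"P00141","andes","PER","2002-08-09",1
"P00142","andes","PER","2008-03-05",1
"P00143","andes","PER","2007-12-01",1
"P00144","vanguard","BRA","2010-10-10",0
"P00145","vanguard","BRA","2007-04-07",1
"P00146","andes","PER","2006-01-26",0
"P00147","andes","PER","2008-12-19",1
"P00148","vanguard","BRA","2007-04-13",0
"P00149","andes","PER","2010-07-16",0
"P00150","andes","PER","2011-04-11",0
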