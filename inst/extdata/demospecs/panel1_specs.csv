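name,specification,details
id,patient,Unique identifier in datasets
longtablename,lab_cd4,Table name (same as CSV name during data load)
longvar,cd4_v,Longitudinal variable name
longvardate,cd4_d,Longitudinal variable date name
longsubset,cd4_v > 0 and not missing(cd4_v),Keep positive non-missing values
eventtablename,follow,Table holding the event flag and end date
event,death_y,Event variable name
enddate,l_alive_d,End date name
grouptablename,basic,Table holding the classifier
group,aids_y,Grouping variable name
starttablename,art,Table holding the start date
startdate,art_sd,Start date name
starttype,first,first or last start date per subject
longvartrans,sqrt,Plotting-scale transformation
maxtime,730,Maximum follow-up in days
long2eventwindow,360,Days a value may precede the event and still mark it
longvarlim,"c(0,1500)",Longitudinal axis limits (original scale)
longticks,"c(0,25,100,150,350,500,1000,2000,5000)",Tick values (original scale)
longlabel,CD4+ Count,Y-axis label for the scatter pane
timelabel,Days from cART Start,Time-axis label
eventlabel,Cumulative Probability of Death,Y-axis label for the event pane
grouplabels,0 = No AIDS|1 = AIDS|9 = AIDS unknown,Legend labels per group value
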